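## Resting-state network identification: template matching of independent
## components and group-level spatial statistics.

#' Template difference score for one component map
#'
#' Mean z value of the voxels inside the template minus the mean z value of
#' the voxels outside it.  Constant maps score zero; adding a constant to
#' the map leaves the score unchanged.
#'
#' @param zMap voxel vector (z-scored component map)
#' @param mask logical voxel vector, neither empty nor all-voxels
#' @return the difference score
#' @export
templateMatchScore <- function(zMap, mask) {
  mask <- as.logical(mask)
  if (length(zMap) != length(mask)) .stopf("map and mask live on different grids")
  nIn <- sum(mask)
  if (nIn == 0L || nIn == length(mask))
    .stopf("template mask must be nonempty and not cover the whole grid")
  mean(zMap[mask]) - mean(zMap[!mask])
}

#' Assign components to networks by template matching
#'
#' Scores every component against every template with
#' [templateMatchScore()] (Pearson spatial correlations are computed
#' alongside and logged) and assigns greedily by descending score: when two
#' templates prefer the same component, the higher-scoring template keeps it
#' and the other falls back to its best remaining component.  A warning is
#' emitted when the difference score and the spatial correlation disagree on
#' a winner.
#'
#' @param ica an [ICAResult-class] (group maps are used) or a k x voxel
#'   matrix of z-scored maps
#' @param templates a [TemplateSet-class]
#' @return an [RSNAssignment-class]
#' @export
assignComponents <- function(ica, templates) {
  maps <- if (is(ica, "ICAResult")) ica@groupMaps else ica
  masks <- templates@masks
  k <- nrow(maps)
  nT <- ncol(masks)
  if (k < nT) .stopf("fewer components (%d) than templates (%d)", k, nT)
  scoreTab <- matrix(NA_real_, k, nT, dimnames = list(NULL, templates@networkNames))
  corTab <- scoreTab
  for (j in seq_len(nT)) {
    m <- masks[, j]
    for (i in seq_len(k)) {
      scoreTab[i, j] <- templateMatchScore(maps[i, ], m)
      corTab[i, j] <- stats::cor(maps[i, ], as.numeric(m))
    }
  }
  assigned <- integer(0)
  res <- data.frame(network = character(nT), component = integer(nT),
                    score = numeric(nT), runnerUp = numeric(nT),
                    correlation = numeric(nT))
  remainingT <- seq_len(nT)
  while (length(remainingT)) {
    ## best available (template, component) pair by difference score
    sub <- scoreTab[, remainingT, drop = FALSE]
    sub[assigned, ] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    tj <- remainingT[best[2]]
    ci <- best[1]
    avail <- setdiff(seq_len(k), c(assigned, ci))
    res[tj, ] <- list(templates@networkNames[tj], ci, scoreTab[ci, tj],
                      if (length(avail)) max(scoreTab[avail, tj]) else -Inf,
                      corTab[ci, tj])
    corBest <- which.max(replace(corTab[, tj], assigned, -Inf))
    if (corBest != ci)
      warning(sprintf("network %s: difference score picks component %d but spatial correlation prefers %d",
                      templates@networkNames[tj], ci, corBest), call. = FALSE)
    assigned <- c(assigned, ci)
    remainingT <- setdiff(remainingT, tj)
  }
  new("RSNAssignment", assignment = res, scoreTable = scoreTab,
      correlationTable = corTab)
}

## vectorized one- and two-sample t tests across voxels
.rowStats <- function(maps) {
  n <- nrow(maps)
  mu <- colMeans(maps)
  v <- (colMeans(maps^2) - mu^2) * n / (n - 1)
  list(n = n, mean = mu, var = pmax(v, 0))
}

#' Voxelwise group t test on subject component maps
#'
#' One-sample mode tests the subject maps against zero; two-sample mode
#' tests high vs low group (pooled-variance t) inside a mandatory analysis
#' mask.  Two-sided p values are Benjamini-Hochberg adjusted over the
#' in-mask voxels at level `q`.  Voxels with zero variance get p = 1 and
#' are listed in the returned log.
#'
#' @param maps subjects x voxel matrix of (z-scored) component maps
#' @param mode `"one_sample"` or `"two_sample"`
#' @param q FDR level
#' @param mask optional logical analysis mask (required for two-sample mode)
#' @param groups factor/character of group labels (two-sample mode)
#' @return list(t, p, padj, sigMask, df, zeroVarVoxels); maps outside the
#'   analysis mask carry NA statistics
#' @export
groupSpatialTTest <- function(maps, mode = c("one_sample", "two_sample"),
                              q = 0.05, mask = NULL, groups = NULL) {
  mode <- match.arg(mode)
  V <- ncol(maps)
  if (is.null(mask)) {
    if (mode == "two_sample") .stopf("two-sample mode requires an analysis mask")
    mask <- rep(TRUE, V)
  }
  mask <- as.logical(mask)
  tStat <- p <- padj <- rep(NA_real_, V)
  if (mode == "one_sample") {
    if (nrow(maps) < 2L) .stopf("need >= 2 subjects")
    st <- .rowStats(maps[, mask, drop = FALSE])
    se <- sqrt(st$var / st$n)
    tv <- st$mean / se
    df <- st$n - 1L
  } else {
    g <- as.character(groups)
    stopifnot(length(g) == nrow(maps))
    lv <- unique(g)
    if (length(lv) != 2L) .stopf("two-sample mode requires exactly two groups")
    m1 <- maps[g == lv[1], mask, drop = FALSE]
    m2 <- maps[g == lv[2], mask, drop = FALSE]
    if (nrow(m1) < 2L || nrow(m2) < 2L) .stopf("need >= 2 subjects per group")
    s1 <- .rowStats(m1); s2 <- .rowStats(m2)
    df <- s1$n + s2$n - 2L
    sp2 <- ((s1$n - 1) * s1$var + (s2$n - 1) * s2$var) / df
    tv <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  }
  zeroVar <- !is.finite(tv)
  pv <- 2 * stats::pt(-abs(tv), df)
  pv[zeroVar] <- 1
  tv[zeroVar] <- 0
  padjv <- stats::p.adjust(pv, method = "BH")
  tStat[mask] <- tv
  p[mask] <- pv
  padj[mask] <- padjv
  sig <- !is.na(padj) & padj <= q
  list(t = tStat, p = p, padj = padj, sigMask = sig, df = df,
       zeroVarVoxels = which(mask)[zeroVar])
}

#' Combine the two groups' significance masks per network
#'
#' The analysis mask for between-group comparison of a network is the
#' voxelwise union of the two groups' one-sample significance masks.
#'
#' @param highMasks,lowMasks logical vectors, or named lists of them
#'   (per network)
#' @return the union mask, or a list of unions when lists were given
#' @export
buildCombinedMask <- function(highMasks, lowMasks) {
  if (is.list(highMasks)) {
    stopifnot(identical(names(highMasks), names(lowMasks)))
    return(mapply(buildCombinedMask, highMasks, lowMasks, SIMPLIFY = FALSE))
  }
  if (length(highMasks) != length(lowMasks)) .stopf("masks live on different grids")
  as.logical(highMasks) | as.logical(lowMasks)
}
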