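## Conditional Granger causality between network time courses: least-squares
## VAR fitting, Schwarz-criterion order selection, Geweke-style conditional
## influence terms, surrogate normalization, and edge-level group tests.

.resolveCols <- function(ts, idx) {
  if (is.character(idx)) {
    out <- match(idx, colnames(ts))
    if (anyNA(out)) .stopf("unknown series: %s", paste(idx[is.na(out)], collapse = ", "))
    out
  } else as.integer(idx)
}

## lagged design block: columns of `cols` at lags 1..m, rows `rows`
.lagBlock <- function(ts, cols, m, rows) {
  do.call(cbind, lapply(seq_len(m), function(l) ts[rows - l, cols, drop = FALSE]))
}

#' Fit a vector autoregression by ordinary least squares
#'
#' Regresses `x_t` on an intercept and `x_{t-1}, ..., x_{t-m}`.  The
#' residual covariance is the residual cross-product divided by the
#' effective sample size, and the Schwarz criterion is
#' `log det(residCov) + (log(Teff)/Teff) * m * d^2`.
#'
#' @param ts time x d numeric matrix
#' @param order model order m
#' @param presample time points reserved at the start (>= `order`); rows
#'   `presample + 1, ..., T` enter the regression, so fits with a common
#'   `presample` share their effective sample
#' @return a [VARFit-class]
#' @export
fitVAR <- function(ts, order, presample = order) {
  ts <- as.matrix(ts)
  m <- as.integer(order)
  d <- ncol(ts)
  Tn <- nrow(ts)
  stopifnot(presample >= m)
  if (Tn <= d * m + presample + 1L)
    .stopf("series too short (T = %d) for order %d with %d variables", Tn, m, d)
  rows <- (presample + 1L):Tn
  X <- cbind(1, .lagBlock(ts, seq_len(d), m, rows))
  Y <- ts[rows, , drop = FALSE]
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10)
    .stopf("ill-conditioned lag design (condition number > 1e10): use a shorter order or a longer series")
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  nEff <- length(rows)
  residCov <- crossprod(res) / nEff
  residCov <- (residCov + t(residCov)) / 2
  sc <- determinant(residCov, logarithm = TRUE)$modulus[1] + log(nEff) / nEff * m * d^2
  coefs <- lapply(seq_len(m), function(l) {
    Al <- t(B[1L + ((l - 1L) * d + 1L):(l * d), , drop = FALSE])
    dimnames(Al) <- list(colnames(ts), colnames(ts))
    Al
  })
  new("VARFit", order = m, coefficients = coefs, intercept = as.numeric(B[1L, ]),
      residCov = residCov, nEffective = as.integer(nEff), sc = as.numeric(sc))
}

#' Select the autoregressive order by the Schwarz criterion
#'
#' Fits orders `1..maxOrder` with the first `maxOrder` points reserved as a
#' common presample, so the criterion values are computed on the identical
#' effective sample, and returns the minimizing order (ties go to the
#' smallest order).
#'
#' @param ts time x d numeric matrix
#' @param maxOrder largest order considered
#' @param returnCurve also return the criterion values
#' @return the selected order, or list(order, sc) when `returnCurve = TRUE`
#' @export
selectOrderSC <- function(ts, maxOrder = 5L, returnCurve = FALSE) {
  stopifnot(maxOrder >= 1L)
  sc <- vapply(seq_len(maxOrder),
               function(m) fitVAR(ts, m, presample = maxOrder)@sc, 0)
  ord <- which.min(sc)
  if (returnCurve) list(order = ord, sc = sc) else as.integer(ord)
}

## residual variance of the target equation in a VAR over `cols`
.targetRSS <- function(ts, cols, tgt, m, rows) {
  X <- cbind(1, .lagBlock(ts, cols, m, rows))
  y <- ts[rows, tgt]
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Conditional Granger causality influence term
#'
#' `F_{source -> target | cond} = log(sigma2_restricted / sigma2_full)`,
#' where the restricted model predicts the target from the past of
#' `{target, cond}` and the full model adds the past of `source`; both are
#' order-`m` least-squares fits on the identical effective sample (first `m`
#' points reserved).  Nonnegative by nesting; tiny negative round-off is
#' clamped to zero.
#'
#' @param ts time x d numeric matrix (columns may be named)
#' @param source source series (index or name; may be a set)
#' @param target single target series
#' @param cond conditioning series (defaults to all remaining columns)
#' @param order model order m
#' @return the influence term F (>= 0)
#' @export
conditionalGC <- function(ts, source, target, cond = NULL, order = 1L) {
  ts <- as.matrix(ts)
  src <- .resolveCols(ts, source)
  tgt <- .resolveCols(ts, target)
  cnd <- if (is.null(cond)) setdiff(seq_len(ncol(ts)), c(src, tgt)) else .resolveCols(ts, cond)
  if (length(tgt) != 1L) .stopf("target must be a single series")
  if (length(intersect(src, c(tgt, cnd))) || length(intersect(tgt, cnd)))
    .stopf("source, target and conditioning sets must be disjoint")
  m <- as.integer(order)
  rows <- (m + 1L):nrow(ts)
  rssR <- .targetRSS(ts, c(tgt, cnd), tgt, m, rows)
  rssF <- .targetRSS(ts, c(tgt, cnd, src), tgt, m, rows)
  f <- log(rssR / rssF)
  stopifnot(f >= -1e-12)
  max(f, 0)
}

#' All ordered-pair conditional influences
#'
#' For every ordered pair of columns, the conditional influence given all
#' remaining columns: `d (d - 1)` directed edges (12 for four networks).
#'
#' @param ts time x d matrix with column names
#' @param order model order
#' @return data.frame(source, target, label, F)
#' @export
gcAllPairs <- function(ts, order = 1L) {
  ts <- as.matrix(ts)
  d <- ncol(ts)
  nms <- colnames(ts)
  if (is.null(nms)) nms <- paste0("N", seq_len(d))
  pairs <- expand.grid(target = seq_len(d), source = seq_len(d))
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  out <- data.frame(source = nms[pairs$source], target = nms[pairs$target],
                    label = paste0(nms[pairs$source], "->", nms[pairs$target]))
  out$F <- mapply(function(s, t) conditionalGC(ts, s, t, order = order),
                  pairs$source, pairs$target)
  rownames(out) <- NULL
  out
}

#' Surrogate-normalized conditional influence
#'
#' Normalizes `F` against a null distribution obtained by circularly
#' shifting the source series by uniformly random offsets of at least
#' `order + 1` samples (which preserves each series' autocorrelation while
#' destroying cross-coupling) and recomputing the influence:
#' `z = (F - mean(F_null)) / sd(F_null)`.
#'
#' @param ts time x d matrix
#' @param source,target,cond,order as in [conditionalGC()]
#' @param nSurrogates number of surrogates (>= 19)
#' @param seed RNG seed (shifts are deterministic given the seed)
#' @return list(F, z, null) with `null` the surrogate influences
#' @export
gcNormalize <- function(ts, source, target, cond = NULL, order = 1L,
                        nSurrogates = 99L, seed = 1L) {
  stopifnot(nSurrogates >= 19L)
  ts <- as.matrix(ts)
  src <- .resolveCols(ts, source)
  F0 <- conditionalGC(ts, src, target, cond, order)
  Tn <- nrow(ts)
  m <- as.integer(order)
  set.seed(seed)
  offsets <- sample((m + 1L):(Tn - m - 1L), nSurrogates, replace = TRUE)
  Fn <- vapply(offsets, function(off) {
    tsS <- ts
    tsS[, src] <- ts[c((off + 1L):Tn, 1L:off), src]
    conditionalGC(tsS, src, target, cond, order)
  }, 0)
  sdn <- stats::sd(Fn)
  if (sdn == 0) .stopf("surrogate null is degenerate (zero spread)")
  list(F = F0, z = (F0 - mean(Fn)) / sdn, null = Fn)
}

#' Per-subject conditional Granger matrix for a cohort
#'
#' Computes all ordered-pair conditional influences and their surrogate
#' normalizations for every subject's network time courses (columns centered
#' per subject before fitting).
#'
#' @param tsList named list of time x d network time-course matrices with
#'   identical column names
#' @param groups group label per subject
#' @param order model order
#' @param nSurrogates surrogates per edge
#' @param seed master seed; per-subject/edge seeds are derived from it
#' @param detrend also remove a linear trend per series (off by default)
#' @return a [GCMatrix-class]
#' @export
gcCohort <- function(tsList, groups, order = 1L, nSurrogates = 99L, seed = 1L,
                     detrend = FALSE) {
  stopifnot(length(tsList) >= 1L, length(groups) == length(tsList))
  ids <- names(tsList)
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(tsList))
  proto <- gcAllPairs(scale(tsList[[1]], scale = FALSE), order = order)
  edges <- proto[c("source", "target", "label")]
  Fm <- matrix(NA_real_, length(tsList), nrow(edges),
               dimnames = list(ids, edges$label))
  Zm <- Fm
  for (i in seq_along(tsList)) {
    ts <- as.matrix(tsList[[i]])
    ts <- scale(ts, scale = FALSE)
    if (detrend) ts <- apply(ts, 2, function(y) stats::lsfit(seq_along(y), y)$residuals)
    for (e in seq_len(nrow(edges))) {
      gz <- gcNormalize(ts, edges$source[e], edges$target[e], order = order,
                        nSurrogates = nSurrogates,
                        seed = deriveSeed(seed, "gc", ids[i], edges$label[e]))
      Fm[i, e] <- gz$F
      Zm[i, e] <- gz$z
    }
  }
  new("GCMatrix", edges = edges, influence = Fm, zscores = Zm,
      order = as.integer(order), subjectIds = ids, groups = as.character(groups))
}

#' Edge-level one-sample group test on normalized influences
#'
#' Per group and edge, a two-sided one-sample t test of the normalized
#' values against zero, Benjamini-Hochberg adjusted across the edges within
#' each group at level `q`.  (The raw F is nonnegative by construction, so
#' the test acts on the surrogate-normalized z, which is centered under the
#' null.)
#'
#' @param gc a [GCMatrix-class], or a subjects x edges matrix of z values
#' @param q FDR level
#' @param groups group labels (when `gc` is a plain matrix); a single
#'   common group is assumed if omitted
#' @return data.frame(group, edge, meanZ, t, p, padj, significant,
#'   degenerate)
#' @export
groupGCTest <- function(gc, q = 0.05, groups = NULL) {
  if (is(gc, "GCMatrix")) {
    z <- gc@zscores
    groups <- gc@groups
  } else {
    z <- as.matrix(gc)
    if (is.null(groups)) groups <- rep("all", nrow(z))
  }
  out <- NULL
  for (g in unique(groups)) {
    zg <- z[groups == g, , drop = FALSE]
    if (nrow(zg) < 2L) .stopf("need >= 2 subjects in group %s", g)
    mu <- colMeans(zg)
    se <- apply(zg, 2, stats::sd) / sqrt(nrow(zg))
    degenerate <- se == 0
    tv <- ifelse(degenerate, 0, mu / se)
    pv <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tv), nrow(zg) - 1L))
    padj <- stats::p.adjust(pv, method = "BH")
    out <- rbind(out, data.frame(group = g, edge = colnames(z), meanZ = mu,
                                 t = tv, p = pv, padj = padj,
                                 significant = padj <= q,
                                 degenerate = degenerate, row.names = NULL))
  }
  out
}
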