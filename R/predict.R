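## Behavioral correlation screen and leave-one-out SVR prediction.

#' Pearson correlation with its two-sided p value
#'
#' Sample Pearson r with the usual t transform on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance
#' @return list(r, p)
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) .stopf("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values with enforced monotonicity, plus the
#' significance mask at level `q`.
#'
#' @param pvals p values in `[0, 1]`
#' @param q FDR level
#' @return list(padj, significant)
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) .stopf("p values must lie in [0, 1]")
  padj <- stats::p.adjust(pvals, method = "BH")
  list(padj = padj, significant = padj <= q)
}

#' Leave-one-out SVR prediction of a behavioral score
#'
#' For each subject, a linear-kernel epsilon-SVR is trained on the remaining
#' subjects — with features standardized by the training fold's statistics
#' only — and predicts the held-out subject.  Features that are constant in
#' a training fold are dropped for that fold and logged.  The fold
#' construction and linear solve contain no randomness, so the result is
#' deterministic.
#'
#' @param features subjects x f numeric matrix (edge z values)
#' @param scores the behavioral score to predict
#' @param C SVR cost parameter
#' @param epsilon epsilon-insensitive tube width
#' @param edge label stored with the result
#' @return a [PredictionResult-class] with per-fold predictions, RMSEP, and
#'   the Pearson correlation of predicted vs actual
#' @export
svrLoocvPredict <- function(features, scores, C = 1, epsilon = 0.1, edge = "feature") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3L) .stopf("need at least 3 subjects")
  stopifnot(length(scores) == n)
  pred <- numeric(n)
  dropped <- list()
  for (i in seq_len(n)) {
    trX <- features[-i, , drop = FALSE]
    trY <- scores[-i]
    mu <- colMeans(trX)
    sd <- apply(trX, 2, stats::sd)
    keep <- sd > 0
    if (!all(keep))
      dropped[[length(dropped) + 1L]] <- list(fold = i, features = which(!keep))
    if (!any(keep)) { pred[i] <- mean(trY); next }
    trZ <- sweep(sweep(trX[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep], "/")
    teZ <- (features[i, keep] - mu[keep]) / sd[keep]
    fit <- e1071::svm(trZ, trY, type = "eps-regression", kernel = "linear",
                      cost = C, epsilon = epsilon, scale = FALSE)
    pred[i] <- stats::predict(fit, matrix(teZ, nrow = 1L))
  }
  rm <- sqrt(mean((pred - scores)^2))
  ct <- pearsonCorr(pred, scores)
  new("PredictionResult", predicted = pred, actual = as.numeric(scores),
      rmsep = rm, r = ct$r, p = ct$p, edge = edge, droppedFeatures = dropped)
}

#' Correlation screen of connectivity against behavioral scales
#'
#' Per group, Pearson correlations between each edge-of-interest's
#' normalized influence and each behavioral scale, with Benjamini-Hochberg
#' adjustment within the group's edge x scale family.
#'
#' @param gc a [GCMatrix-class]
#' @param behavioral data.frame with `subjectId`, `group`, and the scales;
#'   rows must match the GC matrix subjects
#' @param q FDR level
#' @param edges edge labels screened (default: the modulation candidates
#'   AfN->VN and DAN->VAN)
#' @param scales scale names screened
#' @return data.frame(group, edge, scale, r, p, padj, significant)
#' @export
correlationScreen <- function(gc, behavioral, q = 0.05,
                              edges = c("AfN->VN", "DAN->VAN"),
                              scales = behavioralScales()) {
  stopifnot(is(gc, "GCMatrix"))
  if (!identical(as.character(behavioral$subjectId), gc@subjectIds))
    .stopf("behavioral table and GC matrix subjects are misaligned")
  missingE <- setdiff(edges, gc@edges$label)
  if (length(missingE)) .stopf("unknown edges: %s", paste(missingE, collapse = ", "))
  out <- NULL
  for (g in unique(gc@groups)) {
    sel <- gc@groups == g
    rows <- expand.grid(edge = edges, scale = scales, stringsAsFactors = FALSE)
    rows$group <- g
    rp <- mapply(function(e, sc) {
      unlist(pearsonCorr(gc@zscores[sel, e], behavioral[[sc]][sel]))
    }, rows$edge, rows$scale)
    rows$r <- rp["r", ]
    rows$p <- rp["p", ]
    adj <- fdrBH(rows$p, q)
    rows$padj <- adj$padj
    rows$significant <- adj$significant
    out <- rbind(out, rows[c("group", "edge", "scale", "r", "p", "padj", "significant")])
  }
  rownames(out) <- NULL
  out
}
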