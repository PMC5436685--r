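## Temporal-concatenation group spatial ICA: latent-dimension estimation,
## PCA reduction, FastICA unmixing, and dual-regression back-reconstruction.

#' Estimate the number of latent components by minimum description length
#'
#' Wax-Kailath MDL on the eigenspectrum of the data covariance.  With
#' `p = min(nrow, ncol)` and `N = max(nrow, ncol)` the criterion over
#' candidate dimensionalities `k = 0, ..., p - 1` is
#' \deqn{MDL(k) = -N (p-k) \log\frac{g_k}{a_k} + \frac{1}{2} k (2p - k) \log N}
#' where `g_k` and `a_k` are the geometric and arithmetic means of the
#' smallest `p - k` eigenvalues; the estimate is the minimizing `k`.
#'
#' @param x numeric time x voxel matrix (orientation is immaterial: the
#'   smaller dimension is treated as the observed vector dimension)
#' @param returnCurve also return the full criterion curve
#' @return the estimated dimension (integer), or a list(k, mdl) when
#'   `returnCurve = TRUE`
#' @export
estimateNdimMDL <- function(x, returnCurve = FALSE) {
  if (nrow(x) < 2L || ncol(x) < 2L) .stopf("need at least a 2 x 2 matrix")
  .assertFinite(x, "data")
  Y <- if (nrow(x) <= ncol(x)) x else t(x)
  N <- ncol(Y)
  Y <- Y - rowMeans(Y)
  C <- tcrossprod(Y) / N
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ## restrict to the numerical rank: MDL is undefined over zero eigenvalues
  tolRank <- max(ev) * length(ev) * .Machine$double.eps
  ev <- ev[ev > tolRank]
  p <- length(ev)
  logev <- log(ev)
  ## suffix cumulations of log-eigenvalues and eigenvalues
  csLog <- rev(cumsum(rev(logev)))
  csLin <- rev(cumsum(rev(ev)))
  k <- 0:(p - 1)
  g <- csLog[k + 1] / (p - k)               # log geometric mean
  a <- log(csLin[k + 1] / (p - k))          # log arithmetic mean
  mdl <- -N * (p - k) * (g - a) + 0.5 * k * (2 * p - k) * log(N)
  kHat <- k[which.min(mdl)]
  if (returnCurve) list(k = kHat, mdl = mdl) else kHat
}

#' Concatenate subjects along time and reduce by PCA
#'
#' Stacks the subjects' time x voxel matrices along time, centers each voxel
#' column across concatenated time, and retains the top-`k` spatial
#' principal directions in a single reduction stage.  The returned operators
#' are sufficient to locate every subject's block and to reconstruct the
#' centered data at full rank.
#'
#' @param subjectData list of [SubjectDataset-class] or plain time x voxel
#'   matrices on a common grid
#' @param k retained components; must not exceed the numerical rank
#' @param normalizeVariance also scale each voxel column to unit variance
#'   before reduction (off by default: centering only)
#' @return list(reduced = concatenated-time x k matrix,
#'   ops = [ReductionOperators-class])
#' @export
concatAndReduce <- function(subjectData, k, normalizeVariance = FALSE) {
  mats <- lapply(subjectData, function(s) if (is(s, "SubjectDataset")) s@data else s)
  V <- unique(vapply(mats, ncol, 0L))
  if (length(V) != 1L) .stopf("subjects disagree on voxel count: %s", paste(V, collapse = ", "))
  if (k > V) .stopf("k = %d exceeds the voxel count %d", k, V)
  rows <- cumsum(c(0L, vapply(mats, nrow, 0L)))
  X <- do.call(rbind, mats)
  ctr <- colMeans(X)
  X <- sweep(X, 2L, ctr)
  sds <- rep(1, ncol(X))
  if (normalizeVariance) {
    sds <- sqrt(.colVars(X))
    sds[sds < 1e-12] <- 1
    X <- sweep(X, 2L, sds, "/")
  }
  Tt <- nrow(X)
  ## eigendecompose the smaller cross-product
  if (Tt <= V) {
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    tolRank <- max(eg$values) * Tt * .Machine$double.eps
    rank <- sum(eg$values > tolRank)
    if (k > rank) .stopf("k = %d exceeds the numerical rank %d", k, rank)
    dvals <- sqrt(eg$values[seq_len(k)])
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    basis <- crossprod(X, U) %*% diag(1 / dvals, k)
    reduced <- U %*% diag(dvals, k)
    allEv <- pmax(eg$values, 0) / (Tt - 1)
  } else {
    eg <- eigen(crossprod(X), symmetric = TRUE)
    tolRank <- max(eg$values) * V * .Machine$double.eps
    rank <- sum(eg$values > tolRank)
    if (k > rank) .stopf("k = %d exceeds the numerical rank %d", k, rank)
    basis <- eg$vectors[, seq_len(k), drop = FALSE]
    dvals <- sqrt(eg$values[seq_len(k)])
    reduced <- X %*% basis
    allEv <- pmax(eg$values, 0) / (Tt - 1)
  }
  blocks <- lapply(seq_along(mats), function(i) (rows[i] + 1L):rows[i + 1L])
  names(blocks) <- if (!is.null(names(subjectData))) names(subjectData) else
    sprintf("subject%02d", seq_along(mats))
  ops <- new("ReductionOperators", basis = basis, center = ctr, scale = sds,
             singularValues = dvals, eigenvalues = dvals^2 / (Tt - 1),
             allEigenvalues = allEv, rowBlocks = blocks)
  list(reduced = reduced, ops = ops)
}

#' FastICA by symmetric fixed-point iteration
#'
#' Classic FastICA with the `tanh` contrast on a mixtures-by-samples matrix:
#' rows of `x` are observed mixed signals, columns are samples (for spatial
#' ICA, voxels).  The data are whitened internally; the unmixing matrix is
#' updated by `W <- E[g(WZ) Z'] - diag(E[g'(WZ)]) W` followed by symmetric
#' orthogonalization `W <- (W W')^{-1/2} W`, until the maximum rowwise
#' `|1 - |diag(W_new W_old')||` drops below `tol` or `maxIter` is reached.
#' Non-convergence is reported in the result, not raised as an error.  Sign
#' and order of the recovered sources are arbitrary.
#'
#' @param x k x n matrix of mixtures (rows = mixed signals)
#' @param k number of components (defaults to `nrow(x)`)
#' @param seed seed for the random orthogonal initialization
#' @param tol convergence tolerance
#' @param maxIter iteration cap
#' @return list(S = k x n unit-variance sources, W = unmixing (applied to
#'   whitened data), K = whitening matrix, A = k x k mixing in the original
#'   mixture space, center = row means removed, converged, iterations,
#'   finalDelta)
#' @export
fasticaDecompose <- function(x, k = nrow(x), seed = 1L, tol = 1e-6, maxIter = 500L) {
  stopifnot(is.matrix(x), k <= nrow(x))
  x <- x[seq_len(k), , drop = FALSE] * 1
  n <- ncol(x)
  ctr <- rowMeans(x)
  xc <- x - ctr
  C <- tcrossprod(xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) <= max(eg$values) * 1e-12)
    .stopf("mixtures are rank deficient; reduce k")
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- K %*% xc
  ## seeded random orthogonal init (QR of a Gaussian matrix)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  iter <- 0L
  delta <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wnew <- tcrossprod(G, Z) / n - diag(rowMeans(1 - G^2), k) %*% W
    ## symmetric orthogonalization
    sv <- eigen(tcrossprod(Wnew), symmetric = TRUE)
    Wnew <- sv$vectors %*% diag(1 / sqrt(sv$values)) %*% t(sv$vectors) %*% Wnew
    delta <- max(abs(1 - abs(diag(Wnew %*% t(W)))))
    W <- Wnew
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- solve(K[seq_len(k), , drop = FALSE]) %*% t(W)   # x_c ~ A S
  list(S = S, W = W, K = K, A = A, center = ctr,
       converged = delta < tol, iterations = iter, finalDelta = delta)
}

#' Z-score component maps rowwise
#'
#' Transforms each row (one component's voxel map) to zero mean and unit
#' standard deviation, so map intensities read as standardized connectivity
#' weights.
#'
#' @param maps k x voxel matrix
#' @return the standardized matrix
#' @export
zscoreMaps <- function(maps) {
  mu <- rowMeans(maps)
  sd <- sqrt(rowMeans((maps - mu)^2))
  if (any(sd < 1e-300)) .stopf("zero-variance map row(s): %s",
                               paste(which(sd < 1e-300), collapse = ", "))
  (maps - mu) / sd
}

#' Group-level spatial ICA of reduced data
#'
#' Runs FastICA on the reduced representation so that the estimated sources
#' are spatial maps (voxels as samples) and the mixing columns are the group
#' time courses.  Returns an [ICAResult-class] with the group fields filled;
#' subject fields are added by [backReconstruct()].
#'
#' @param reduced concatenated-time x k matrix from [concatAndReduce()]
#' @param ops the matching [ReductionOperators-class]
#' @param seed,tol,maxIter passed to [fasticaDecompose()]
#' @return an [ICAResult-class] (group fields only)
#' @export
groupICADecompose <- function(reduced, ops, seed = 1L, tol = 1e-6, maxIter = 500L) {
  k <- ncol(reduced)
  ## mixtures in voxel space: D V' (k x voxel); X_c = U (D V')
  mixtures <- t(ops@basis %*% diag(ops@singularValues, k))
  fi <- fasticaDecompose(mixtures, k = k, seed = seed, tol = tol, maxIter = maxIter)
  ## resolve the sign ambiguity: orient every spatial map to positive
  ## skewness (the conventional choice, making focal sources load positively)
  sgn <- ifelse(rowMeans(fi$S^3) < 0, -1, 1)
  fi$S <- fi$S * sgn
  fi$W <- fi$W * sgn
  fi$A <- sweep(fi$A, 2L, sgn, "*")
  ## X_c = U * mixtures ~ U A S  =>  time courses = U A = reduced D^{-1} A
  tc <- reduced %*% diag(1 / ops@singularValues, k) %*% fi$A
  new("ICAResult", nComponents = as.integer(k),
      groupMaps = zscoreMaps(fi$S),
      groupTimecourses = tc, unmixing = fi$W, whitening = fi$K, mixing = fi$A,
      subjectMaps = list(), subjectTimecourses = list(),
      convergence = fi[c("converged", "iterations", "finalDelta")],
      reduction = ops)
}

#' Back-reconstruct subject maps and time courses
#'
#' Subject time courses are the subject's block of the reduced data pushed
#' through the group decomposition; subject maps are obtained by regressing
#' the subject's centered voxel data onto those time courses (dual
#' regression), then z-scored.
#'
#' @param ica an [ICAResult-class] from [groupICADecompose()]
#' @param subjectData the same subject list given to [concatAndReduce()]
#' @return the [ICAResult-class] with `subjectMaps` and
#'   `subjectTimecourses` filled
#' @export
backReconstruct <- function(ica, subjectData) {
  ops <- ica@reduction
  k <- ica@nComponents
  proj <- diag(1 / ops@singularValues, k) %*% ica@mixing
  maps <- vector("list", length(subjectData))
  tcs <- vector("list", length(subjectData))
  nms <- names(ops@rowBlocks)
  for (i in seq_along(subjectData)) {
    s <- subjectData[[i]]
    Xi <- if (is(s, "SubjectDataset")) s@data else s
    ## the subject's block of the reduced data uses the group centering
    Ri <- sweep(sweep(Xi, 2L, ops@center), 2L, ops@scale, "/") %*% ops@basis
    Ti <- Ri %*% proj
    ## maps regress the subject-centered data on the subject time courses
    Xi <- sweep(Xi, 2L, colMeans(Xi))
    ctp <- crossprod(Ti)
    cond <- tryCatch(kappa(ctp, exact = FALSE), error = function(e) Inf)
    if (!is.finite(cond) || cond > 1e12)
      .stopf("singular time-course cross-product for subject %s", nms[i])
    Si <- solve(ctp, crossprod(Ti, Xi))
    maps[[i]] <- zscoreMaps(Si)
    tcs[[i]] <- Ti
  }
  names(maps) <- names(tcs) <- nms
  ica@subjectMaps <- maps
  ica@subjectTimecourses <- tcs
  ica
}

#' Spatially subsampled MDL dimension estimate
#'
#' Spatial smoothing correlates neighboring voxels, violating the i.i.d.
#' sample assumption behind the description-length criterion and inflating
#' the estimate.  Subsampling the voxel grid at a stride comparable to the
#' smoothing kernel's FWHM restores approximately independent samples
#' (the usual i.i.d.-sampling correction).
#'
#' @param x time x voxel matrix, voxels in grid (column-major) order
#' @param grid the [VoxelGrid-class] the columns live on
#' @param strideVox subsampling stride in voxels (per axis, recycled)
#' @return the estimated dimension
#' @export
estimateNdimMDLGrid <- function(x, grid, strideVox = 1L) {
  strideVox <- pmax(1L, rep_len(as.integer(strideVox), 3L))
  if (all(strideVox == 1L)) return(estimateNdimMDL(x))
  d <- grid@dims
  stopifnot(ncol(x) == prod(d))
  keep <- as.vector(array(seq_len(prod(d)), d)[seq(1L, d[1], strideVox[1]),
                                               seq(1L, d[2], strideVox[2]),
                                               seq(1L, d[3], strideVox[3])])
  estimateNdimMDL(x[, keep, drop = FALSE])
}

#' Full group ICA convenience wrapper
#'
#' Concatenation, optional MDL dimension estimation, PCA reduction, FastICA,
#' and back-reconstruction in one call.
#'
#' @param subjectData list of [SubjectDataset-class] or matrices
#' @param k number of components, or `"mdl"` to estimate it
#' @param maxK cap applied to an MDL estimate (keeps the decomposition at a
#'   tractable size when smoothed noise inflates the estimate)
#' @param grid optional [VoxelGrid-class]; with `mdlStride > 1` the MDL
#'   estimate uses [estimateNdimMDLGrid()] on a voxel subsample
#' @param mdlStride stride for the i.i.d.-sampling correction
#' @param seed,tol,maxIter FastICA controls
#' @param normalizeVariance passed to [concatAndReduce()]
#' @return an [ICAResult-class] with subject fields filled
#' @export
groupICA <- function(subjectData, k = "mdl", maxK = 40L, grid = NULL,
                     mdlStride = 1L, seed = 1L,
                     tol = 1e-6, maxIter = 500L, normalizeVariance = FALSE) {
  if (identical(k, "mdl")) {
    X <- do.call(rbind, lapply(subjectData,
                               function(s) if (is(s, "SubjectDataset")) s@data else s))
    kEst <- if (!is.null(grid) && any(mdlStride > 1L))
      estimateNdimMDLGrid(X, grid, mdlStride) else estimateNdimMDL(X)
    k <- max(2L, min(kEst, maxK))
  }
  red <- concatAndReduce(subjectData, k, normalizeVariance = normalizeVariance)
  ica <- groupICADecompose(red$reduced, red$ops, seed = seed, tol = tol, maxIter = maxIter)
  backReconstruct(ica, subjectData)
}
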