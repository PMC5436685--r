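## Synthetic resting-state cohort generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: spatially disjoint network sources mixed into voxel data, VAR(1)
## coupled network time courses, and behavioral scores linked to directed
## coupling strengths.  It makes no attempt at hemodynamics, motion or
## physiological noise (see the methods vignette).

.colVars <- function(x) {
  n <- nrow(x)
  (colMeans(x^2) - colMeans(x)^2) * n / (n - 1)
}

#' Build disjoint spherical network templates
#'
#' Places `blobsPerNetwork` spherical blobs per network by rejection
#' sampling, so that masks are nonempty and pairwise disjoint across
#' networks.  A stand-in for downloaded functional network templates: the
#' analysis only needs named binary masks on the common grid.
#'
#' @param grid a [VoxelGrid-class]
#' @param nNetworks number of networks
#' @param networkNames labels; default DAN, VAN, AfN, VN (then N5, N6, ...)
#' @param blobsPerNetwork spherical blobs per network
#' @param blobRadius sphere radius in voxels (Euclidean, inclusive)
#' @param seed RNG seed (placement is deterministic given the seed)
#' @param maxAttempts rejection-sampling budget per blob
#' @param avoid optional logical voxel vector of positions the blobs must
#'   not touch (used to keep nuisance supports off the network masks)
#' @return a [TemplateSet-class]
#' @examples
#' tpl <- makeTemplates(voxelGrid(c(20, 20, 10)), seed = 7)
#' colSums(templateMasks(tpl))
#' @export
makeTemplates <- function(grid, nNetworks = 4L,
                          networkNames = c("DAN", "VAN", "AfN", "VN"),
                          blobsPerNetwork = 2L, blobRadius = 2,
                          seed = 1L, maxAttempts = 5000L, avoid = NULL) {
  stopifnot(is(grid, "VoxelGrid"))
  if (length(networkNames) < nNetworks)
    networkNames <- c(networkNames, paste0("N", seq_len(nNetworks)))[seq_len(nNetworks)]
  networkNames <- networkNames[seq_len(nNetworks)]
  d <- grid@dims
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  taken <- if (is.null(avoid)) logical(nrow(coords)) else as.logical(avoid)
  masks <- matrix(FALSE, nrow(coords), nNetworks, dimnames = list(NULL, networkNames))
  set.seed(seed)
  for (net in seq_len(nNetworks)) {
    for (b in seq_len(blobsPerNetwork)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        ctr <- c(sample(d[1], 1L), sample(d[2], 1L), sample(d[3], 1L))
        dist2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 + (coords[, 3] - ctr[3])^2
        inBlob <- dist2 <= blobRadius^2
        if (!any(inBlob)) next
        ## disjointness is enforced across networks only
        if (any(taken & inBlob & !masks[, net])) next
        masks[inBlob, net] <- TRUE
        taken <- taken | inBlob
        placed <- TRUE
        break
      }
      if (!placed)
        .stopf("could not place blob %d of network %s: grid too small for the requested templates", b, networkNames[net])
    }
  }
  new("TemplateSet", grid = grid, masks = masks, networkNames = networkNames)
}

#' Construct a coupling specification
#'
#' @param A square lag-1 coefficient matrix (`A[i, j]`: influence of network
#'   j on network i one step later); spectral radius must be < 1
#' @param networks network labels
#' @param noiseSd innovation standard deviation
#' @param modulatedEdges data.frame(source, target, slope): edges whose
#'   effective strength is `A[target, source] + slope * (score - scoreRef)`
#' @param scoreRef reference Loneliness score
#' @param clampRange saturation range for modulated entries
#' @return a [CouplingSpec-class]
#' @export
couplingSpec <- function(A, networks = colnames(A), noiseSd = 1,
                         modulatedEdges = data.frame(source = character(),
                                                     target = character(),
                                                     slope = numeric()),
                         scoreRef = 55, clampRange = c(0.05, 0.9)) {
  if (is.null(networks)) networks <- paste0("N", seq_len(nrow(A)))
  dimnames(A) <- list(networks, networks)
  new("CouplingSpec", networks = networks, A = A, noiseSd = noiseSd,
      modulatedEdges = modulatedEdges, scoreRef = scoreRef,
      clampRange = as.numeric(clampRange))
}

#' The default four-network coupling specification
#'
#' DAN, VAN, AfN, VN with self-coupling 0.3 and directed couplings
#' AfN->VN = 0.45, DAN->VAN = 0.45, AfN->VAN = 0.35, DAN->VN = 0.35 at the
#' reference score.  AfN->VN and DAN->VAN weaken with the Loneliness score
#' (slope -0.025 per point, saturating at the clamp range); the slope is
#' sized so that the coupling-score relation is recoverable from 15
#' subjects per group (see the methods vignette for the power calculation).
#'
#' @param slope modulation slope per Loneliness point
#' @return a [CouplingSpec-class]
#' @export
defaultCouplingSpec <- function(slope = -0.025) {
  nets <- c("DAN", "VAN", "AfN", "VN")
  A <- diag(0.3, 4)
  dimnames(A) <- list(nets, nets)
  A["VN", "AfN"] <- 0.45
  A["VAN", "DAN"] <- 0.45
  A["VAN", "AfN"] <- 0.35
  A["VN", "DAN"] <- 0.35
  couplingSpec(A, nets,
               modulatedEdges = data.frame(source = c("AfN", "DAN"),
                                           target = c("VN", "VAN"),
                                           slope = slope))
}

#' Effective coupling matrix at a given behavioral score
#'
#' Applies every modulated edge of `spec` at `score` and clamps the
#' modulated entries to the saturation range.
#'
#' @param spec a [CouplingSpec-class]
#' @param score the subject's Loneliness score
#' @return the effective lag-1 coefficient matrix
#' @export
effectiveCoupling <- function(spec, score) {
  A <- spec@A
  me <- spec@modulatedEdges
  for (i in seq_len(nrow(me))) {
    v <- A[me$target[i], me$source[i]] + me$slope[i] * (score - spec@scoreRef)
    A[me$target[i], me$source[i]] <- min(max(v, spec@clampRange[1]), spec@clampRange[2])
  }
  A
}

#' Simulate VAR(1)-coupled network time courses
#'
#' Generates `x_t = A_eff x_{t-1} + eps_t` with i.i.d. Gaussian innovations
#' after discarding `burnIn` steps, where `A_eff` is
#' [effectiveCoupling()] at `score`.
#'
#' @param spec a [CouplingSpec-class]
#' @param score Loneliness score modulating the coupled edges
#' @param nSteps time points returned
#' @param burnIn initial steps discarded (transient removal)
#' @param seed RNG seed
#' @return an `nSteps` x d matrix with network column names
#' @export
simulateNetworkTimecourses <- function(spec, score = spec@scoreRef, nSteps,
                                       burnIn = 50L, seed = 1L) {
  stopifnot(nSteps >= 1L)
  A <- effectiveCoupling(spec, score)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    .stopf("effective coupling at score %g is non-stationary (spectral radius >= 1)", score)
  d <- length(spec@networks)
  set.seed(seed)
  eps <- matrix(stats::rnorm((nSteps + burnIn) * d, sd = spec@noiseSd), nSteps + burnIn, d)
  X <- matrix(0, nSteps + burnIn, d, dimnames = list(NULL, spec@networks))
  x <- numeric(d)
  for (t in seq_len(nSteps + burnIn)) {
    x <- drop(A %*% x) + eps[t, ]
    X[t, ] <- x
  }
  X[(burnIn + 1):(burnIn + nSteps), , drop = FALSE]
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `Sigma = A Sigma A' + Q` by
#' fixed-point iteration.  Used as the analytic reference for the simulated
#' lag structure.
#'
#' @param A lag-1 coefficient matrix (spectral radius < 1)
#' @param Q innovation covariance
#' @param tol convergence tolerance
#' @return the stationary covariance matrix
#' @export
var1StationaryCov <- function(A, Q, tol = 1e-12) {
  S <- Q
  for (i in seq_len(10000L)) {
    S2 <- A %*% S %*% t(A) + Q
    if (max(abs(S2 - S)) < tol) return(S2)
    S <- S2
  }
  S
}

## Cohort-level spatial loadings, deterministic in the master seed: every
## subject shares the same in-mask loading pattern (the group map the ICA
## should find), nuisance sources get sparse out-of-mask supports.
.cohortLoadings <- function(cfg) {
  set.seed(deriveSeed(cfg@masterSeed, "loadings"))
  V <- prod(cfg@grid@dims)
  masks <- cfg@templates@masks
  dNet <- ncol(masks)
  M <- matrix(0, dNet + cfg@nNuisance, V)
  for (j in seq_len(dNet))
    M[j, masks[, j]] <- stats::runif(sum(masks[, j]), 0.5, 1)
  if (cfg@nNuisance > 0L) {
    ## nuisance sources get compact blob supports of their own, disjoint
    ## from the network masks (scanner/physiological artifact stand-ins)
    nui <- makeTemplates(cfg@grid, nNetworks = cfg@nNuisance,
                         networkNames = paste0("nuis", seq_len(cfg@nNuisance)),
                         seed = deriveSeed(cfg@masterSeed, "nuisance-supports"),
                         avoid = rowSums(masks) > 0L)
    for (j in seq_len(cfg@nNuisance)) {
      sup <- nui@masks[, j]
      M[dNet + j, sup] <- stats::runif(sum(sup), 0.5, 1)
    }
  }
  M
}

#' Simulate one subject's voxel data
#'
#' Mixes the subject's VAR(1) network time courses (modulated by the
#' Loneliness score) and AR(1) nuisance sources through the cohort's spatial
#' loadings, and adds i.i.d. Gaussian noise scaled so that the mean in-mask
#' temporal signal variance over the noise variance equals `cfg@snr`.
#'
#' @param cfg a [CohortConfig-class]
#' @param scores named numeric vector over [behavioralScales()]
#' @param group "high" or "low"; must be consistent with the Loneliness score
#' @param subjectId identifier
#' @param seed RNG seed for this subject
#' @param loadings optional precomputed cohort loading matrix (internal
#'   reuse across subjects; must come from `.cohortLoadings(cfg)`)
#' @return a [SubjectDataset-class] with `cfg@nVolumesRaw` volumes
#' @export
simulateSubject <- function(cfg, scores, group, subjectId = "s01", seed = 1L,
                            loadings = NULL) {
  if (!all(behavioralScales() %in% names(scores)))
    .stopf("scores must contain all of: %s", paste(behavioralScales(), collapse = ", "))
  lon <- scores[["Loneliness"]]
  if ((group == "high" && lon <= 45) || (group == "low" && lon >= 28))
    .stopf("group '%s' inconsistent with Loneliness score %g (high > 45, low < 28)", group, lon)
  Tn <- cfg@nVolumesRaw
  M <- if (is.null(loadings)) .cohortLoadings(cfg) else loadings
  dNet <- length(cfg@coupling@networks)
  Snet <- simulateNetworkTimecourses(cfg@coupling, score = lon, nSteps = Tn,
                                     seed = deriveSeed(seed, "timecourses"))
  set.seed(deriveSeed(seed, "nuisance"))
  S <- cbind(Snet, matrix(0, Tn, cfg@nNuisance))
  for (j in seq_len(cfg@nNuisance)) {
    e <- stats::rnorm(Tn + 50L)
    S[, dNet + j] <- stats::filter(e, 0.3, method = "recursive")[51:(Tn + 50L)]
  }
  signal <- S %*% M
  inMask <- rowSums(cfg@templates@masks) > 0L
  vsig <- mean(.colVars(signal[, inMask, drop = FALSE]))
  noiseSd <- if (is.finite(cfg@snr)) sqrt(vsig / cfg@snr) else 0
  set.seed(deriveSeed(seed, "noise"))
  data <- signal + matrix(stats::rnorm(length(signal), sd = noiseSd), nrow(signal))
  new("SubjectDataset", data = data, tr = cfg@tr,
      behavioral = scores[behavioralScales()], group = group,
      subjectId = subjectId, seed = as.integer(seed))
}

#' Discard initial volumes
#'
#' Removes the first `n` volumes of a subject's run (signal-equilibration
#' convention for the opening seconds of an acquisition).
#'
#' @param ds a [SubjectDataset-class]
#' @param n number of leading volumes to drop; must be < `nVolumes(ds)`
#' @return the shortened [SubjectDataset-class]
#' @export
discardInitialVolumes <- function(ds, n = 5L) {
  if (n >= nVolumes(ds))
    .stopf("cannot discard %d of %d volumes", n, nVolumes(ds))
  if (n == 0L) return(ds)
  ds@data <- ds@data[-seq_len(n), , drop = FALSE]
  ds
}

## 1-D Gaussian convolution matrix with half-sample symmetric (reflective)
## boundary handling.
.gaussKernelMatrix <- function(n, sigmaVox) {
  if (sigmaVox < 1e-8) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  w <- stats::dnorm(-r:r, sd = sigmaVox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  reflect <- function(j) {
    j <- (j - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  for (i in seq_len(n)) {
    idx <- reflect(i + (-r:r))
    for (t in seq_along(idx)) K[i, idx[t]] <- K[i, idx[t]] + w[t]
  }
  K
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume with a separable Gaussian of the given full width
#' at half maximum (`sigma = fwhm / (2 sqrt(2 ln 2))` per axis, in mm,
#' converted to voxels through the grid's voxel size).  Boundaries are
#' handled by symmetric reflection, which preserves the per-volume sum.
#'
#' @param ds a [SubjectDataset-class]
#' @param grid the [VoxelGrid-class] the data live on
#' @param fwhmMm kernel FWHM in mm (0 returns the input unchanged)
#' @return the smoothed [SubjectDataset-class]
#' @export
smoothSpatial <- function(ds, grid, fwhmMm = 8) {
  if (fwhmMm < 0) .stopf("fwhmMm must be nonnegative")
  if (fwhmMm == 0) return(ds)
  d <- grid@dims
  stopifnot(ncol(ds@data) == prod(d))
  sigmaMm <- fwhmMm / (2 * sqrt(2 * log(2)))
  Ks <- lapply(1:3, function(a) .gaussKernelMatrix(d[a], sigmaMm / grid@voxelSize[a]))
  Tn <- nrow(ds@data)
  arr <- array(t(ds@data), c(d, Tn))
  ## axis 1
  arr <- array(Ks[[1]] %*% matrix(arr, d[1]), c(d, Tn))
  ## axis 2
  arr <- aperm(array(Ks[[2]] %*% matrix(aperm(arr, c(2, 1, 3, 4)), d[2]),
                     c(d[2], d[1], d[3], Tn)), c(2, 1, 3, 4))
  ## axis 3
  arr <- aperm(array(Ks[[3]] %*% matrix(aperm(arr, c(3, 1, 2, 4)), d[3]),
                     c(d[3], d[1], d[2], Tn)), c(2, 3, 1, 4))
  ds@data <- t(matrix(arr, prod(d), Tn))
  ds
}

.defaultScoreRanges <- function() list(
  Loneliness = list(high = 46:65, low = 20:27),
  STAI  = 30:60,
  SDS   = 30:57,   # exclusion rule keeps SDS below 60
  IRI_C = 40:70,
  Trust = 60:100,
  SSRS  = 30:50
)

#' Construct a cohort configuration
#'
#' Defaults mirror the study design the analysis expects: 15 subjects per
#' group, 255 volumes at TR 2 s with the first 5 discarded, four coupled
#' networks plus two nuisance sources, in-mask SNR 2, a 24 x 24 x 12 grid of
#' 3 mm voxels.
#'
#' @param nHigh,nLow subjects per group
#' @param nVolumesRaw acquired volumes per subject
#' @param nDiscard leading volumes to discard
#' @param tr repetition time (seconds)
#' @param grid a [VoxelGrid-class]
#' @param templates a [TemplateSet-class]; built from the grid if missing
#' @param coupling a [CouplingSpec-class]
#' @param snr in-mask signal variance over noise variance
#' @param nNuisance number of nuisance sources
#' @param scoreRanges per-scale integer sampling ranges
#' @param masterSeed master seed
#' @return a [CohortConfig-class]
#' @export
cohortConfig <- function(nHigh = 15L, nLow = 15L, nVolumesRaw = 255L,
                         nDiscard = 5L, tr = 2, grid = voxelGrid(),
                         templates = NULL, coupling = defaultCouplingSpec(),
                         snr = 2, nNuisance = 2L,
                         scoreRanges = .defaultScoreRanges(),
                         masterSeed = 1L) {
  if (is.null(templates))
    templates <- makeTemplates(grid, nNetworks = length(coupling@networks),
                               networkNames = coupling@networks,
                               seed = deriveSeed(masterSeed, "templates"))
  new("CohortConfig", nHigh = as.integer(nHigh), nLow = as.integer(nLow),
      nVolumesRaw = as.integer(nVolumesRaw), nDiscard = as.integer(nDiscard),
      tr = tr, grid = grid, templates = templates, coupling = coupling,
      snr = snr, nNuisance = as.integer(nNuisance), scoreRanges = scoreRanges,
      masterSeed = as.integer(masterSeed))
}

#' Simulate a full cohort
#'
#' Samples behavioral scores per group (Loneliness above 45 for the high
#' group, below 28 for the low group; the other five scales independently of
#' Loneliness and of group), then simulates every subject with a sub-seed
#' derived from the master seed.  The per-subject effective coupling
#' matrices are retained as ground truth.
#'
#' @param cfg a [CohortConfig-class]
#' @return a [Cohort-class]
#' @export
simulateCohort <- function(cfg) {
  n <- cfg@nHigh + cfg@nLow
  groups <- rep(c("high", "low"), c(cfg@nHigh, cfg@nLow))
  ids <- sprintf("sub-%02d", seq_len(n))
  sr <- cfg@scoreRanges
  set.seed(deriveSeed(cfg@masterSeed, "scores"))
  beh <- data.frame(subjectId = ids, group = groups)
  beh$Loneliness <- ifelse(groups == "high",
                           sample(sr$Loneliness$high, n, replace = TRUE),
                           sample(sr$Loneliness$low, n, replace = TRUE))
  for (sc in setdiff(behavioralScales(), "Loneliness"))
    beh[[sc]] <- sample(sr[[sc]], n, replace = TRUE)
  beh$seed <- vapply(ids, function(id) deriveSeed(cfg@masterSeed, "subject", id), 0L)
  subjectsList <- vector("list", n)
  truth <- vector("list", n)
  loadings <- .cohortLoadings(cfg)
  for (i in seq_len(n)) {
    scores <- unlist(beh[i, behavioralScales()])
    subjectsList[[i]] <- simulateSubject(cfg, scores, groups[i], ids[i], beh$seed[i],
                                         loadings = loadings)
    truth[[i]] <- effectiveCoupling(cfg@coupling, scores[["Loneliness"]])
  }
  names(subjectsList) <- names(truth) <- ids
  new("Cohort", subjects = subjectsList, behavioral = beh,
      couplingTruth = truth, config = cfg)
}

#' Planted independent-source data for dimensionality checks
#'
#' Mixes `nSources` i.i.d. Gaussian source time courses per subject into the
#' voxel grid through disjoint sparse spatial supports shared across
#' subjects, plus i.i.d. noise at the requested in-support SNR, and
#' concatenates subjects along time.  This is the fixture on which the
#' latent-dimension estimate should recover `nSources` exactly.
#'
#' @param nSources number of planted sources
#' @param nSubjects subjects concatenated
#' @param nTimepoints time points per subject
#' @param grid a [VoxelGrid-class]
#' @param supportVoxels voxels in each source's support
#' @param snr in-support signal variance over noise variance
#' @param seed RNG seed
#' @return list(data = concatenated time x voxel matrix, loadings = nSources
#'   x voxel matrix, blocks = per-subject row ranges)
#' @export
simulateSourceData <- function(nSources = 40L, nSubjects = 6L, nTimepoints = 150L,
                               grid = voxelGrid(), supportVoxels = 60L,
                               snr = 2, seed = 1L) {
  V <- prod(grid@dims)
  if (nSources * supportVoxels > V)
    .stopf("grid too small: %d sources x %d voxels of support > %d voxels",
           nSources, supportVoxels, V)
  set.seed(seed)
  idx <- sample.int(V, nSources * supportVoxels)
  M <- matrix(0, nSources, V)
  for (j in seq_len(nSources))
    M[j, idx[((j - 1) * supportVoxels + 1):(j * supportVoxels)]] <- stats::runif(supportVoxels, 0.5, 1)
  inSup <- colSums(M) > 0
  blocks <- vector("list", nSubjects)
  X <- matrix(0, nSubjects * nTimepoints, V)
  for (s in seq_len(nSubjects)) {
    S <- matrix(stats::rnorm(nTimepoints * nSources), nTimepoints, nSources)
    sig <- S %*% M
    vsig <- mean(.colVars(sig[, inSup, drop = FALSE]))
    rows <- ((s - 1) * nTimepoints + 1):(s * nTimepoints)
    X[rows, ] <- sig + matrix(stats::rnorm(nTimepoints * V, sd = sqrt(vsig / snr)),
                              nTimepoints, V)
    blocks[[s]] <- rows
  }
  list(data = X, loadings = M, blocks = blocks)
}
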