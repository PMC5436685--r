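## S4 classes for the resting-state effective-connectivity toolchain.

#' The six behavioral scales carried by a simulated subject
#'
#' Loneliness (UCLA-type total score, defines the high/low groups), STAI
#' (anxiety), SDS (depression), IRI_C (empathy), Trust, and SSRS (social
#' support).
#'
#' @return character vector of scale names
#' @export
behavioralScales <- function() c("Loneliness", "STAI", "SDS", "IRI_C", "Trust", "SSRS")

#' VoxelGrid: the common 3-D sampling grid
#'
#' @slot dims integer triple (nx, ny, nz)
#' @slot voxelSize positive mm triple
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", voxelSize = "numeric"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("dims must be three integers >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive reals (mm)")
    TRUE
  }
)

#' Construct a VoxelGrid
#'
#' @param dims integer triple (nx, ny, nz); default 24 x 24 x 12
#' @param voxelSize voxel edge length(s) in mm; recycled to length 3
#' @return a [VoxelGrid-class] object
#' @export
voxelGrid <- function(dims = c(24L, 24L, 12L), voxelSize = 3) {
  new("VoxelGrid", dims = as.integer(dims), voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' TemplateSet: named binary network masks on a shared grid
#'
#' @slot grid the common [VoxelGrid-class]
#' @slot masks logical voxel x network matrix, one column per network
#' @slot networkNames unique network labels (column names of `masks`)
#' @export
setClass("TemplateSet",
  representation(grid = "VoxelGrid", masks = "matrix", networkNames = "character"),
  validity = function(object) {
    if (!is.logical(object@masks)) return("masks must be a logical matrix")
    if (nrow(object@masks) != prod(object@grid@dims))
      return("masks row count must equal the grid voxel count")
    if (ncol(object@masks) != length(object@networkNames))
      return("one mask column per network name required")
    if (anyDuplicated(object@networkNames)) return("network names must be unique")
    if (any(colSums(object@masks) == 0L)) return("every mask must be nonempty")
    TRUE
  }
)

#' CouplingSpec: lag-1 network coupling with behavioral modulation
#'
#' Entry `A[i, j]` is the influence of network `j` at time t-1 on network
#' `i` at time t.  `modulatedEdges` ties named directed edges to a subject's
#' Loneliness score: the effective entry is
#' `A[target, source] + slope * (score - scoreRef)`, clamped elementwise to
#' `clampRange` (a saturation that keeps extreme scores physiological).
#'
#' @slot networks network labels (rows/cols of `A`)
#' @slot A square lag-1 coefficient matrix with spectral radius < 1
#' @slot noiseSd innovation standard deviation (> 0)
#' @slot modulatedEdges data.frame(source, target, slope)
#' @slot scoreRef reference score at which `A` applies unchanged
#' @slot clampRange length-2 clamp for modulated entries
#' @export
setClass("CouplingSpec",
  representation(networks = "character", A = "matrix", noiseSd = "numeric",
                 modulatedEdges = "data.frame", scoreRef = "numeric",
                 clampRange = "numeric"),
  validity = function(object) {
    d <- length(object@networks)
    if (!all(dim(object@A) == d)) return("A must be square with one row per network")
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    if (max(Mod(eigen(object@A, only.values = TRUE)$values)) >= 1)
      return("A must have spectral radius < 1 (stationarity)")
    if (nrow(object@modulatedEdges) &&
        !all(c("source", "target", "slope") %in% names(object@modulatedEdges)))
      return("modulatedEdges needs columns source, target, slope")
    bad <- setdiff(unlist(object@modulatedEdges[c("source", "target")]), object@networks)
    if (length(bad)) return(paste("unknown networks in modulatedEdges:", paste(bad, collapse = ", ")))
    TRUE
  }
)

#' SubjectDataset: one subject's time x voxel data plus behavioral scores
#'
#' @slot data numeric time x voxel matrix (rows = volumes)
#' @slot tr repetition time in seconds
#' @slot behavioral named numeric vector over [behavioralScales()]
#' @slot group "high" or "low" loneliness group
#' @slot subjectId identifier
#' @slot seed the seed the subject was generated from
#' @export
setClass("SubjectDataset",
  representation(data = "matrix", tr = "numeric", behavioral = "numeric",
                 group = "character", subjectId = "character", seed = "integer"),
  validity = function(object) {
    if (!object@group %in% c("high", "low")) return("group must be 'high' or 'low'")
    if (!all(behavioralScales() %in% names(object@behavioral)))
      return("behavioral must contain all six scales")
    lon <- object@behavioral[["Loneliness"]]
    if (object@group == "high" && lon <= 45)
      return("high group requires Loneliness > 45")
    if (object@group == "low" && lon >= 28)
      return("low group requires Loneliness < 28")
    TRUE
  }
)

#' CohortConfig: everything needed to simulate a cohort
#'
#' @slot nHigh,nLow subjects per group (>= 2)
#' @slot nVolumesRaw volumes acquired per subject (default 255)
#' @slot nDiscard initial volumes discarded for signal equilibration (default 5)
#' @slot tr repetition time in seconds (default 2)
#' @slot grid the [VoxelGrid-class]
#' @slot templates the [TemplateSet-class] of network supports
#' @slot coupling the [CouplingSpec-class]
#' @slot snr in-mask signal variance / noise variance (default 2)
#' @slot nNuisance number of nuisance sources mixed in (default 2)
#' @slot scoreRanges named list of integer sampling ranges per scale;
#'   Loneliness has separate `high` and `low` ranges
#' @slot masterSeed master seed; all subject seeds derive from it
#' @export
setClass("CohortConfig",
  representation(nHigh = "integer", nLow = "integer", nVolumesRaw = "integer",
                 nDiscard = "integer", tr = "numeric", grid = "VoxelGrid",
                 templates = "TemplateSet", coupling = "CouplingSpec",
                 snr = "numeric", nNuisance = "integer", scoreRanges = "list",
                 masterSeed = "integer"),
  validity = function(object) {
    if (object@nHigh < 2L || object@nLow < 2L) return("nHigh and nLow must be >= 2")
    if (object@nDiscard >= object@nVolumesRaw) return("nDiscard must be < nVolumesRaw")
    if (object@snr <= 0) return("snr must be positive")
    if (prod(object@templates@grid@dims) != prod(object@grid@dims))
      return("templates must live on the cohort grid")
    TRUE
  }
)

#' Cohort: simulated subjects, their behavioral table, and the ground truth
#'
#' @slot subjects list of [SubjectDataset-class]
#' @slot behavioral data.frame(subjectId, group, six scales, seed)
#' @slot couplingTruth per-subject effective coupling matrices (the ground
#'   truth against which recovery is judged)
#' @slot config the generating [CohortConfig-class]
#' @export
setClass("Cohort",
  representation(subjects = "list", behavioral = "data.frame",
                 couplingTruth = "list", config = "CohortConfig"))

#' ReductionOperators: the group PCA reduction and its bookkeeping
#'
#' @slot basis voxel x k matrix of retained spatial principal directions
#' @slot center voxelwise means removed before reduction
#' @slot scale voxelwise divisors applied before reduction (all 1 unless
#'   variance normalization was requested)
#' @slot singularValues the k retained singular values of the centered data
#' @slot eigenvalues retained covariance eigenvalues (non-increasing)
#' @slot allEigenvalues the full computed eigenspectrum
#' @slot rowBlocks named list of row index ranges, one per subject
#' @export
setClass("ReductionOperators",
  representation(basis = "matrix", center = "numeric", scale = "numeric",
                 singularValues = "numeric",
                 eigenvalues = "numeric", allEigenvalues = "numeric",
                 rowBlocks = "list"))

#' ICAResult: group decomposition plus per-subject back-reconstructions
#'
#' @slot nComponents number of independent components k
#' @slot groupMaps k x voxel source (spatial) maps, z-scored
#' @slot groupTimecourses concatenated-time x k mixing time courses
#' @slot unmixing k x k unmixing applied to the whitened mixtures
#' @slot whitening k x k whitening operator
#' @slot mixing k x k mixing in reduced space
#' @slot subjectMaps per subject, k x voxel z-scored maps
#' @slot subjectTimecourses per subject, time x k matrix
#' @slot convergence list(converged, iterations, finalDelta)
#' @slot reduction the [ReductionOperators-class] used
#' @export
setClass("ICAResult",
  representation(nComponents = "integer", groupMaps = "matrix",
                 groupTimecourses = "matrix", unmixing = "matrix",
                 whitening = "matrix", mixing = "matrix",
                 subjectMaps = "list", subjectTimecourses = "list",
                 convergence = "list", reduction = "ReductionOperators"))

#' RSNAssignment: which component is which network
#'
#' @slot assignment data.frame(network, component, score, runnerUp, correlation)
#' @slot scoreTable component x network matrix of template difference scores
#' @slot correlationTable component x network Pearson spatial correlations
#' @export
setClass("RSNAssignment",
  representation(assignment = "data.frame", scoreTable = "matrix",
                 correlationTable = "matrix"),
  validity = function(object) {
    if (anyDuplicated(object@assignment$component))
      return("components must be assigned to at most one network")
    TRUE
  }
)

#' GCMatrix: per-subject directed conditional Granger influences
#'
#' Columns are the 12 ordered network pairs "source->target"; `influence`
#' holds the raw F values (nonnegative), `zscores` the surrogate-normalized
#' values.
#'
#' @slot edges data.frame(source, target, label)
#' @slot influence subjects x edges matrix of F values
#' @slot zscores subjects x edges matrix of normalized values
#' @slot order the autoregressive order used
#' @slot subjectIds,groups subject bookkeeping
#' @export
setClass("GCMatrix",
  representation(edges = "data.frame", influence = "matrix", zscores = "matrix",
                 order = "integer", subjectIds = "character", groups = "character"),
  validity = function(object) {
    if (any(object@influence < 0)) return("influence terms must be nonnegative")
    if (!all(dim(object@influence) == dim(object@zscores)))
      return("influence and zscores must be conformable")
    if (ncol(object@influence) != nrow(object@edges))
      return("one column per ordered edge required")
    TRUE
  }
)

#' VARFit: a least-squares multivariate autoregressive fit
#'
#' @slot order model order m
#' @slot coefficients list of m d x d lag matrices
#' @slot intercept length-d intercept
#' @slot residCov d x d residual covariance (cross-product / nEffective)
#' @slot nEffective time points entering the regression
#' @slot sc Schwarz criterion value
#' @export
setClass("VARFit",
  representation(order = "integer", coefficients = "list", intercept = "numeric",
                 residCov = "matrix", nEffective = "integer", sc = "numeric"),
  validity = function(object) {
    if (length(object@coefficients) != object@order)
      return("need one coefficient matrix per lag")
    if (!isTRUE(all.equal(object@residCov, t(object@residCov), tolerance = 1e-8)))
      return("residCov must be symmetric")
    TRUE
  }
)

#' PredictionResult: leave-one-out SVR prediction of a behavioral score
#'
#' @slot predicted per-subject held-out predictions
#' @slot actual the observed scores
#' @slot rmsep root-mean-square error of prediction
#' @slot r,p Pearson correlation of predicted vs actual and its p value
#' @slot edge label of the feature edge(s) used
#' @slot droppedFeatures log of features dropped in any fold
#' @export
setClass("PredictionResult",
  representation(predicted = "numeric", actual = "numeric", rmsep = "numeric",
                 r = "numeric", p = "numeric", edge = "character",
                 droppedFeatures = "list"),
  validity = function(object) {
    if (length(object@predicted) != length(object@actual))
      return("one prediction per subject required")
    if (object@rmsep < 0) return("rmsep must be nonnegative")
    TRUE
  }
)

#' PipelineConfig: one object driving a full run
#'
#' @slot cohort the [CohortConfig-class]
#' @slot ica list(k, tol, maxIter, subsets)
#' @slot identify list(q)
#' @slot cgca list(maxOrder, fixedOrder, nSurrogates, q)
#' @slot predict list(C, epsilon, edges)
#' @slot smoothFwhm spatial smoothing FWHM in mm (0 disables)
#' @slot outDir output directory ("" keeps everything in memory)
#' @slot masterSeed master seed for the whole run
#' @export
setClass("PipelineConfig",
  representation(cohort = "CohortConfig", ica = "list", identify = "list",
                 cgca = "list", predict = "list", smoothFwhm = "numeric",
                 outDir = "character", masterSeed = "integer"))
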