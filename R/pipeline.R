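## End-to-end orchestration: simulate -> preprocess -> group ICA ->
## network identification -> conditional GC -> group statistics ->
## behavioral screen -> prediction, with derived seeds and a run manifest.

.stageOrder <- c("simulate", "preprocess", "ica", "identify", "cgca",
                 "stats", "predict")
.stageDeps <- list(simulate = character(0), preprocess = "simulate",
                   ica = "preprocess", identify = "ica", cgca = "identify",
                   stats = "cgca", predict = "stats")

#' Construct a pipeline configuration
#'
#' @param cohort a [CohortConfig-class]
#' @param ica list: `k` (integer or "mdl"), `maxK`, `tol`, `maxIter`,
#'   `subsets` (any of "all", "high", "low"; conditional GC and prediction
#'   always use the "all" decomposition)
#' @param identify list: `q` (FDR level for spatial maps)
#' @param cgca list: `order` (fixed order, or NULL to select by the Schwarz
#'   criterion), `maxOrder`, `nSurrogates`, `q`
#' @param predict list: `C`, `epsilon`, `edges` (features, one model each)
#' @param smoothFwhm spatial smoothing FWHM in mm (0 disables)
#' @param outDir where artifacts are written ("" keeps results in memory)
#' @param masterSeed master seed; every stochastic stage consumes a seed
#'   derived from it
#' @return a [PipelineConfig-class]
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           ica = list(), identify = list(), cgca = list(),
                           predict = list(), smoothFwhm = 8,
                           outDir = "", masterSeed = 1L) {
  ## like modifyList, but an explicit NULL stays a NULL entry
  merge <- function(def, val) {
    for (n in names(val)) def[n] <- list(val[[n]])
    def
  }
  ica <- merge(list(k = "mdl", maxK = 40L, tol = 1e-6,
                    maxIter = 500L, subsets = "all"), ica)
  identify <- merge(list(q = 0.05), identify)
  cgca <- merge(list(order = NULL, maxOrder = 5L,
                     nSurrogates = 99L, q = 0.05), cgca)
  predict <- merge(list(C = 1, epsilon = 0.1,
                        edges = c("AfN->VN", "DAN->VAN")), predict)
  new("PipelineConfig", cohort = cohort, ica = ica, identify = identify,
      cgca = cgca, predict = predict, smoothFwhm = smoothFwhm,
      outDir = outDir, masterSeed = as.integer(masterSeed))
}

.configAsList <- function(cfg) {
  co <- cfg@cohort
  cp <- co@coupling
  list(
    cohort = list(nHigh = co@nHigh, nLow = co@nLow, nVolumesRaw = co@nVolumesRaw,
                  nDiscard = co@nDiscard, tr = co@tr, snr = co@snr,
                  nNuisance = co@nNuisance, masterSeed = co@masterSeed,
                  grid = list(dims = co@grid@dims, voxelSize = co@grid@voxelSize),
                  coupling = list(networks = cp@networks,
                                  A = apply(unname(cp@A), 1, as.list),
                                  noiseSd = cp@noiseSd,
                                  scoreRef = cp@scoreRef,
                                  clampRange = cp@clampRange,
                                  modulatedEdges = cp@modulatedEdges),
                  scoreRanges = co@scoreRanges),
    ica = cfg@ica, identify = cfg@identify, cgca = cfg@cgca,
    predict = cfg@predict, smoothFwhm = cfg@smoothFwhm,
    outDir = cfg@outDir, masterSeed = cfg@masterSeed)
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg a [PipelineConfig-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(.configAsList(cfg), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Rebuilds the full configuration, including the cohort's templates (which
#' derive deterministically from the cohort seed), so that
#' `readPipelineConfig(writePipelineConfig(cfg, f))` equals `cfg`.
#'
#' @param path a YAML file written by [writePipelineConfig()]
#' @return a [PipelineConfig-class]
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  co <- y$cohort
  grid <- voxelGrid(co$grid$dims, co$grid$voxelSize)
  me <- as.data.frame(co$coupling$modulatedEdges)
  if (!nrow(me)) me <- data.frame(source = character(), target = character(),
                                  slope = numeric())
  A <- do.call(rbind, lapply(co$coupling$A, unlist))
  coupling <- couplingSpec(A, networks = co$coupling$networks,
                           noiseSd = co$coupling$noiseSd, modulatedEdges = me,
                           scoreRef = co$coupling$scoreRef,
                           clampRange = unlist(co$coupling$clampRange))
  sr <- co$scoreRanges
  sr$Loneliness <- lapply(sr$Loneliness, unlist)
  sr[setdiff(names(sr), "Loneliness")] <-
    lapply(sr[setdiff(names(sr), "Loneliness")], unlist)
  cohort <- cohortConfig(nHigh = co$nHigh, nLow = co$nLow,
                         nVolumesRaw = co$nVolumesRaw, nDiscard = co$nDiscard,
                         tr = co$tr, grid = grid, coupling = coupling,
                         snr = co$snr, nNuisance = co$nNuisance,
                         scoreRanges = sr, masterSeed = co$masterSeed)
  pipelineConfig(cohort = cohort, ica = y$ica, identify = y$identify,
                 cgca = y$cgca, predict = y$predict, smoothFwhm = y$smoothFwhm,
                 outDir = if (is.null(y$outDir)) "" else y$outDir,
                 masterSeed = y$masterSeed)
}

.manifestAdd <- function(state, stage, t0, outputs, seeds = list()) {
  state$manifest$stages[[stage]] <- list(
    wallSeconds = as.numeric(Sys.time() - t0, units = "secs"),
    checksums = lapply(outputs, function(o) hashObject(.fingerprint(o))),
    seeds = seeds)
  invisible(state)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `preprocess`, `ica`, `identify`, `cgca`, `stats`,
#' `predict`.  Results accumulate in `state`; running a stage whose
#' upstream artifact is missing raises an error naming the stage to run
#' first.
#'
#' @param name stage label
#' @param cfg a [PipelineConfig-class]
#' @param state environment carrying upstream artifacts (as returned by a
#'   previous call); a fresh one is created if omitted
#' @return the state environment, invisibly
#' @export
runStage <- function(name, cfg, state = new.env(parent = emptyenv())) {
  name <- match.arg(name, .stageOrder)
  if (is.null(state$manifest))
    state$manifest <- list(configHash = hashObject(.configAsList(cfg)),
                           stages = list())
  for (dep in .stageDeps[[name]])
    if (is.null(state[[dep]]))
      .stopf("stage '%s' requires stage '%s' to run first", name, dep)
  t0 <- Sys.time()
  seed <- cfg@masterSeed
  switch(name,
    simulate = {
      state$simulate <- simulateCohort(cfg@cohort)
      .manifestAdd(state, name, t0, list(cohort = state$simulate),
                   list(master = cfg@cohort@masterSeed))
    },
    preprocess = {
      grid <- cfg@cohort@grid
      state$preprocess <- lapply(subjects(state$simulate), function(s)
        smoothSpatial(discardInitialVolumes(s, cfg@cohort@nDiscard),
                      grid, cfg@smoothFwhm))
      .manifestAdd(state, name, t0, list(subjects = state$preprocess))
    },
    ica = {
      beh <- behavioralScores(state$simulate)
      seeds <- list()
      state$ica <- list()
      for (subset in cfg@ica$subsets) {
        keep <- if (subset == "all") rep(TRUE, nrow(beh)) else beh$group == subset
        s <- deriveSeed(seed, "ica", subset)
        seeds[[subset]] <- s
        k <- cfg@ica$k
        if (identical(k, "mdl")) {
          ## smoothing correlates voxel samples and inflates the
          ## description-length estimate, so the dimension is estimated on
          ## the unsmoothed (discarded-only) data
          raw <- do.call(rbind, lapply(subjects(state$simulate)[keep], function(x)
            discardInitialVolumes(x, cfg@cohort@nDiscard)@data))
          k <- max(2L, min(estimateNdimMDL(raw), cfg@ica$maxK))
        }
        state$ica[[subset]] <- groupICA(state$preprocess[keep], k = k,
                                        maxK = cfg@ica$maxK,
                                        seed = s, tol = cfg@ica$tol,
                                        maxIter = cfg@ica$maxIter)
      }
      .manifestAdd(state, name, t0, state$ica, seeds)
    },
    identify = {
      templates <- cfg@cohort@templates
      beh <- behavioralScores(state$simulate)
      q <- cfg@identify$q
      state$identify <- list()
      for (subset in names(state$ica))
        state$identify[[subset]] <- assignComponents(state$ica[[subset]], templates)
      ## spatial group statistics from the all-subjects decomposition
      ref <- if ("all" %in% names(state$ica)) "all" else names(state$ica)[1]
      ica <- state$ica[[ref]]
      asg <- assignmentTable(state$identify[[ref]])
      spatial <- list()
      for (j in seq_len(nrow(asg))) {
        comp <- asg$component[j]
        maps <- do.call(rbind, lapply(subjectMaps(ica), function(m) m[comp, ]))
        oneHigh <- groupSpatialTTest(maps[beh$group == "high", , drop = FALSE],
                                     "one_sample", q = q)
        oneLow <- groupSpatialTTest(maps[beh$group == "low", , drop = FALSE],
                                    "one_sample", q = q)
        combined <- buildCombinedMask(oneHigh$sigMask, oneLow$sigMask)
        two <- if (any(combined))
          groupSpatialTTest(maps, "two_sample", q = q, mask = combined,
                            groups = beh$group) else NULL
        spatial[[asg$network[j]]] <- list(oneSampleHigh = oneHigh,
                                          oneSampleLow = oneLow,
                                          combinedMask = combined,
                                          twoSample = two)
      }
      state$identify$spatial <- spatial
      .manifestAdd(state, name, t0, state$identify["spatial"])
    },
    cgca = {
      beh <- behavioralScores(state$simulate)
      ref <- if ("all" %in% names(state$ica)) "all" else names(state$ica)[1]
      ica <- state$ica[[ref]]
      asg <- assignmentTable(state$identify[[ref]])
      comps <- asg$component[match(networkNames(cfg@cohort@templates), asg$network)]
      tsList <- lapply(subjectTimecourses(ica), function(tc) {
        m <- tc[, comps, drop = FALSE]
        colnames(m) <- networkNames(cfg@cohort@templates)
        m
      })
      order <- cfg@cgca$order
      if (is.null(order)) {
        sel <- vapply(tsList, selectOrderSC, 0L, maxOrder = cfg@cgca$maxOrder)
        order <- as.integer(names(which.max(table(sel))))
        state$orderSelection <- sel
      }
      s <- deriveSeed(seed, "cgca")
      state$cgca <- gcCohort(tsList, groups = beh$group, order = order,
                             nSurrogates = cfg@cgca$nSurrogates, seed = s)
      .manifestAdd(state, name, t0, list(gc = state$cgca), list(cgca = s))
    },
    stats = {
      beh <- behavioralScores(state$simulate)
      state$stats <- list(
        edgeTest = groupGCTest(state$cgca, q = cfg@cgca$q),
        screen = correlationScreen(state$cgca, beh, q = cfg@cgca$q,
                                   edges = cfg@predict$edges))
      .manifestAdd(state, name, t0, state$stats)
    },
    predict = {
      beh <- behavioralScores(state$simulate)
      high <- beh$group == "high"
      z <- gcZ(state$cgca)
      state$predict <- lapply(cfg@predict$edges, function(e)
        svrLoocvPredict(z[high, e, drop = FALSE], beh$Loneliness[high],
                        C = cfg@predict$C, epsilon = cfg@predict$epsilon,
                        edge = e))
      names(state$predict) <- cfg@predict$edges
      .manifestAdd(state, name, t0, state$predict)
    })
  invisible(state)
}

#' Run the full pipeline
#'
#' Executes every stage in order and, when `cfg@outDir` is set, writes the
#' main artifacts (assignment and edge tables, screen, prediction, manifest)
#' under it.
#'
#' @param cfg a [PipelineConfig-class]
#' @param stages stages to run, in order
#' @return the state environment with all stage results and `$manifest`
#' @export
runPipeline <- function(cfg, stages = .stageOrder) {
  state <- new.env(parent = emptyenv())
  for (s in stages) runStage(s, cfg, state)
  if (nzchar(cfg@outDir)) writePipelineArtifacts(cfg, state)
  state
}

#' Write the main pipeline artifacts
#'
#' @param cfg a [PipelineConfig-class] with a nonempty `outDir`
#' @param state a state environment from [runPipeline()]
#' @return the output directory, invisibly
#' @export
writePipelineArtifacts <- function(cfg, state) {
  dir.create(cfg@outDir, recursive = TRUE, showWarnings = FALSE)
  out <- cfg@outDir
  if (!is.null(state$identify)) {
    tabs <- NULL
    for (subset in intersect(names(state$identify), names(state$ica))) {
      tb <- assignmentTable(state$identify[[subset]])
      tb$subset <- subset
      tabs <- rbind(tabs, tb)
    }
    utils::write.table(tabs, file.path(out, "assignment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(state$cgca)) writeGCTable(state$cgca, file.path(out, "gc.tsv"))
  if (!is.null(state$stats)) {
    utils::write.table(state$stats$edgeTest, file.path(out, "edge_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(state$stats$screen, file.path(out, "screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(state$predict))
    jsonlite::write_json(lapply(state$predict, function(p)
      list(edge = p@edge, rmsep = p@rmsep, r = p@r, p = p@p,
           predicted = p@predicted, actual = p@actual)),
      file.path(out, "prediction.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(state$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' One-line textual run report
#'
#' Summarizes the significant edge sets, the flagged behavioral
#' correlations, and the prediction metrics of a completed run as Markdown.
#'
#' @param state a state environment from [runPipeline()]
#' @return a character vector of Markdown lines
#' @export
pipelineReport <- function(state) {
  lines <- c("# Pipeline run report", "")
  if (!is.null(state$stats)) {
    et <- state$stats$edgeTest
    for (g in unique(et$group))
      lines <- c(lines, sprintf("- significant edges (%s): %s", g,
                                paste(et$edge[et$group == g & et$significant],
                                      collapse = ", ")))
    sc <- state$stats$screen
    sig <- sc[sc$significant, ]
    lines <- c(lines, sprintf("- flagged correlations: %s",
                              if (nrow(sig)) paste(sprintf("%s~%s (%s, r=%.2f)",
                                sig$edge, sig$scale, sig$group, sig$r),
                                collapse = "; ") else "none"))
  }
  if (!is.null(state$predict))
    for (p in state$predict)
      lines <- c(lines, sprintf("- prediction [%s]: RMSEP %.3f, r = %.3f (p = %.3g)",
                                p@edge, p@rmsep, p@r, p@p))
  lines
}
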