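## Accessor and show() methods.

#' @rdname rsnflow-accessors
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) prod(x@dims))
#' @rdname rsnflow-accessors
#' @export
setMethod("nVoxels", "TemplateSet", function(x) nrow(x@masks))
#' @rdname rsnflow-accessors
#' @export
setMethod("nVoxels", "SubjectDataset", function(x) ncol(x@data))

#' @rdname rsnflow-accessors
#' @export
setMethod("nVolumes", "SubjectDataset", function(x) nrow(x@data))

#' @rdname rsnflow-accessors
#' @export
setMethod("gridDims", "VoxelGrid", function(x) x@dims)
#' @rdname rsnflow-accessors
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)

#' @rdname rsnflow-accessors
#' @export
setMethod("networkNames", "TemplateSet", function(x) x@networkNames)
#' @rdname rsnflow-accessors
#' @export
setMethod("networkNames", "CouplingSpec", function(x) x@networks)

#' @rdname rsnflow-accessors
#' @export
setMethod("templateMasks", "TemplateSet", function(x) x@masks)

#' @rdname rsnflow-accessors
#' @export
setMethod("behavioralScores", "SubjectDataset", function(x) x@behavioral)
#' @rdname rsnflow-accessors
#' @export
setMethod("behavioralScores", "Cohort", function(x) x@behavioral)

#' @rdname rsnflow-accessors
#' @export
setMethod("subjectGroup", "SubjectDataset", function(x) x@group)
#' @rdname rsnflow-accessors
#' @export
setMethod("subjectId", "SubjectDataset", function(x) x@subjectId)

#' @rdname rsnflow-accessors
#' @export
setMethod("subjects", "Cohort", function(x) x@subjects)

#' @rdname rsnflow-accessors
#' @export
setMethod("nComponents", "ICAResult", function(x) x@nComponents)
#' @rdname rsnflow-accessors
#' @export
setMethod("groupMaps", "ICAResult", function(x) x@groupMaps)
#' @rdname rsnflow-accessors
#' @export
setMethod("subjectMaps", "ICAResult", function(x) x@subjectMaps)
#' @rdname rsnflow-accessors
#' @export
setMethod("subjectTimecourses", "ICAResult", function(x) x@subjectTimecourses)

#' @rdname rsnflow-accessors
#' @export
setMethod("assignmentTable", "RSNAssignment", function(x) x@assignment)

#' @rdname rsnflow-accessors
#' @export
setMethod("gcInfluence", "GCMatrix", function(x) x@influence)
#' @rdname rsnflow-accessors
#' @export
setMethod("gcZ", "GCMatrix", function(x) x@zscores)
#' @rdname rsnflow-accessors
#' @export
setMethod("gcEdges", "GCMatrix", function(x) x@edges)

#' @rdname rsnflow-accessors
#' @export
setMethod("predictedScores", "PredictionResult", function(x) x@predicted)
#' @rdname rsnflow-accessors
#' @export
setMethod("rmsep", "PredictionResult", function(x) x@rmsep)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels at %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(object@voxelSize, collapse = " x ")))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet with %d networks on %s grid\n",
              ncol(object@masks), paste(object@grid@dims, collapse = "x")))
  sizes <- colSums(object@masks)
  for (i in seq_along(object@networkNames))
    cat(sprintf("  %-4s %d voxels\n", object@networkNames[i], sizes[i]))
})

setMethod("show", "CouplingSpec", function(object) {
  cat(sprintf("CouplingSpec over {%s}, noise sd %.3g, spectral radius %.3f\n",
              paste(object@networks, collapse = ", "), object@noiseSd,
              max(Mod(eigen(object@A, only.values = TRUE)$values))))
  if (nrow(object@modulatedEdges)) {
    cat("  modulated edges (slope per Loneliness point):\n")
    for (i in seq_len(nrow(object@modulatedEdges)))
      with(object@modulatedEdges[i, ],
           cat(sprintf("    %s->%s  slope %+g\n", source, target, slope)))
  }
})

setMethod("show", "SubjectDataset", function(object) {
  cat(sprintf("SubjectDataset %s (%s group): %d volumes x %d voxels, TR %.3gs, Loneliness %g\n",
              object@subjectId, object@group, nrow(object@data), ncol(object@data),
              object@tr, object@behavioral[["Loneliness"]]))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@behavioral$group)
  cat(sprintf("Cohort of %d subjects (%s)\n", length(object@subjects),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ICAResult", function(object) {
  cat(sprintf("ICAResult: %d components, %d voxels, %d subjects; %s in %d iterations\n",
              object@nComponents, ncol(object@groupMaps), length(object@subjectMaps),
              if (isTRUE(object@convergence$converged)) "converged" else "NOT converged",
              object@convergence$iterations))
})

setMethod("show", "RSNAssignment", function(object) {
  cat("RSNAssignment:\n")
  print(object@assignment, row.names = FALSE)
})

setMethod("show", "GCMatrix", function(object) {
  cat(sprintf("GCMatrix: %d subjects x %d directed edges (order %d)\n",
              nrow(object@influence), nrow(object@edges), object@order))
  cat(sprintf("  mean z: %s\n", paste(sprintf("%s=%.2f", object@edges$label,
              colMeans(object@zscores)), collapse = ", ")))
})

setMethod("show", "VARFit", function(object) {
  cat(sprintf("VARFit: order %d, %d effective time points, SC %.4f\n",
              object@order, object@nEffective, object@sc))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult [%s]: n = %d folds, RMSEP %.3f, r(pred, actual) = %.3f (p = %.3g)\n",
              paste(object@edge, collapse = "+"), length(object@predicted),
              object@rmsep, object@r, object@p))
})
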