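## Generics.  Accessors are preferred over direct slot access throughout.

#' @name rsnflow-accessors
#' @title Accessors for rsnflow classes
#' @param x an rsnflow object
#' @param ... unused
#' @description Small accessor generics: voxel/volume counts, names, maps,
#'   time courses, influence matrices and prediction summaries.
NULL

#' @rdname rsnflow-accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("templateMasks", function(x) standardGeneric("templateMasks"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("behavioralScores", function(x) standardGeneric("behavioralScores"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("groupMaps", function(x) standardGeneric("groupMaps"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("subjectMaps", function(x) standardGeneric("subjectMaps"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("subjectTimecourses", function(x) standardGeneric("subjectTimecourses"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("gcInfluence", function(x) standardGeneric("gcInfluence"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("gcZ", function(x) standardGeneric("gcZ"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("gcEdges", function(x) standardGeneric("gcEdges"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("predictedScores", function(x) standardGeneric("predictedScores"))

#' @rdname rsnflow-accessors
#' @export
setGeneric("rmsep", function(x) standardGeneric("rmsep"))
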