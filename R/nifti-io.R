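## Standard-format I/O: NIfTI volumes, TSV tables, JSON sidecars.

#' Write a subject's 4-D data as NIfTI
#'
#' Volumes are written with the grid's voxel size in the pixel dimensions
#' and the repetition time as the fourth; the affine is identity-scaled.
#'
#' @param ds a [SubjectDataset-class]
#' @param grid the [VoxelGrid-class] the data live on
#' @param path output path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
writeSubjectNifti <- function(ds, grid, path) {
  d <- grid@dims
  arr <- array(t(ds@data), c(d, nrow(ds@data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid@voxelSize, ds@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D NIfTI back into a time x voxel matrix
#'
#' @param path a NIfTI file written by [writeSubjectNifti()]
#' @return list(data = time x voxel matrix, dims, pixdim)
#' @export
readSubjectNifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  list(data = t(matrix(img, prod(d[1:3]), d[4])), dims = d[1:3],
       pixdim = RNifti::pixdim(img))
}

#' Write a template set as an integer-labelled 3-D NIfTI
#'
#' Voxel value i marks membership in network i (0 = background); masks are
#' disjoint by construction so a single label volume is lossless.
#'
#' @param templates a [TemplateSet-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeTemplatesNifti <- function(templates, path) {
  lab <- integer(nrow(templates@masks))
  for (j in seq_len(ncol(templates@masks))) lab[templates@masks[, j]] <- j
  img <- RNifti::asNifti(array(lab, templates@grid@dims))
  RNifti::pixdim(img) <- templates@grid@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write component maps as a 4-D NIfTI (component as the 4th axis)
#'
#' @param maps k x voxel matrix
#' @param grid the [VoxelGrid-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeMapsNifti <- function(maps, grid, path) {
  arr <- array(t(maps), c(grid@dims, nrow(maps)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid@voxelSize, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Per-subject 4-D NIfTI volumes, the behavioral table as CSV, the template
#' labels, and a JSON sidecar with each subject's true effective coupling
#' matrix (the ground truth for recovery checks).
#'
#' @param cohort a [Cohort-class]
#' @param dir output directory (created if needed)
#' @param gzip write `.nii.gz` (default) or plain `.nii`
#' @return the directory, invisibly
#' @export
writeCohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort@config
  ext <- if (gzip) ".nii.gz" else ".nii"
  for (s in cohort@subjects)
    writeSubjectNifti(s, cfg@grid, file.path(dir, paste0(s@subjectId, ext)))
  utils::write.csv(cohort@behavioral, file.path(dir, "cohort.csv"), row.names = FALSE)
  writeTemplatesNifti(cfg@templates, file.path(dir, paste0("templates", ext)))
  truth <- lapply(cohort@couplingTruth, function(A)
    list(networks = colnames(A), A = unname(apply(A, 1, as.list))))
  jsonlite::write_json(truth, file.path(dir, "coupling_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a GC matrix as a tidy TSV
#'
#' One row per subject x directed edge, with the raw influence, the
#' normalized value, and the order used.
#'
#' @param gc a [GCMatrix-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeGCTable <- function(gc, path) {
  long <- expand.grid(subject = gc@subjectIds, edge = gc@edges$label,
                      stringsAsFactors = FALSE)
  long$group <- gc@groups[match(long$subject, gc@subjectIds)]
  long$F <- as.vector(gc@influence)
  long$z <- as.vector(gc@zscores)
  long$order <- gc@order
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
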