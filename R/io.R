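#' @include phantoms.R
NULL

#' Read a NIfTI-1 label map
#'
#' Reads a 3D label map with voxel spacing taken from the NIfTI header.
#' NIfTI does not record which anatomical end sits at low slice indices,
#' so the slice-axis orientation is supplied by the caller.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param distalEnd which slice-index end is distal; default
#'   \code{"low_index"} (inferior-first axial ordering).
#' @return A [LabelVolume-class].
#' @export
readLabelVolume <- function(path, distalEnd = "low_index") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D label map, got ", length(dim(img)), " dimensions")
  vox <- array(as.integer(round(img)), dim = dim(img))
  LabelVolume(vox, spacingMm = RNifti::pixdim(img)[1:3],
              distalEnd = distalEnd)
}

#' Write a LabelVolume as NIfTI-1
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacingMm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes one NIfTI label map per subject plus a \code{manifest.csv} with
#' the ground-truth record (subject_id, family, length_mm, peak_acsa_mm2,
#' peak_location, analytic_volume_mm3, seed).
#'
#' @param cohortResult the list returned by [generateCohort()].
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohortResult, dir) {
  stopifnot(is.list(cohortResult),
            all(c("volumes", "truth") %in% names(cohortResult)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- cohortResult$truth
  truth$file <- file.path(dir, paste0(truth$subject_id, ".nii.gz"))
  for (i in seq_len(nrow(truth)))
    writeLabelVolume(cohortResult$volumes[[i]], truth$file[i])
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(truth, manifest, row.names = FALSE)
  invisible(manifest)
}
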