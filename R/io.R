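#' Write / read a 4D BOLD volume as NIfTI
#'
#' TR is stored in the fourth pixdim slot; the affine origin is recorded in
#' a JSON sidecar (the toy geometry convention used throughout).
#'
#' @param bold A `bold_4d`.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @return `path` invisibly / a `bold_4d`.
#' @export
write_bold <- function(bold, path) {
  stopifnot(inherits(bold, "bold_4d"))
  img <- RNifti::asNifti(bold$values)
  RNifti::pixdim(img) <- c(bold$geometry$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path, datatype = "float")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(tr_s = bold$tr_s,
         voxel_size_mm = bold$geometry$voxel_size_mm,
         origin_mm = bold$geometry$origin_mm),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  bold_4d(array(as.numeric(img), dim = dim(img)), meta$tr_s,
          atlas_geometry(dim(img)[1:3], meta$voxel_size_mm, meta$origin_mm))
}

#' Write / read a confound table as TSV
#'
#' @param confounds Tibble with the motion/wm/csf columns.
#' @param path TSV path.
#' @export
write_confounds <- function(confounds, path) {
  readr::write_tsv(confounds, path)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
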