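#' Read a volume from disk
#'
#' NIfTI (`.nii` / `.nii.gz`) is the canonical interchange format. Voxel
#' values, spacing (mm) and the world origin (xform translation) are
#' extracted; the array is used in its stored voxel order (no
#' reorientation is applied). Label reads validate that the data are
#' integer-valued.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param labels If `TRUE`, return a [cbct_labels()] (values must be
#'   integer-valued).
#' @return A [cbct_volume()] or [cbct_labels()].
#' @section Errors: unknown file extensions (e.g. NRRD, DICOM directories)
#'   signal `cbctools_error_unsupported_format`; non-integer data read with
#'   `labels = TRUE` signals `cbctools_error_non_integer_labels`.
#' @export
read_volume <- function(path, labels = FALSE) {
  if (dir.exists(path))
    cbct_abort(paste0("directory input (DICOM series) is not supported; ",
                      "convert to NIfTI first: ", path),
               "unsupported_format")
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    cbct_abort(paste0("unsupported volume format (need .nii/.nii.gz): ",
                      path), "unsupported_format")
  if (!file.exists(path))
    cbct_abort(paste0("input file not found: ", path), "missing_input")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    cbct_abort(sprintf("expected a 3D volume, got %d dimensions.",
                       length(dim(arr))), "bad_dims")
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- unname(RNifti::xform(img)[1:3, 4])
  attributes(arr) <- list(dim = dim(arr))
  if (labels) {
    if (any(arr != round(arr)))
      cbct_abort("file contains non-integer values; cannot read as labels.",
                 "non_integer_labels")
    cbct_labels(arr, spacing = spacing, origin = origin)
  } else {
    cbct_volume(arr, spacing = spacing, origin = origin)
  }
}

#' Write a volume to NIfTI
#'
#' Spacing and origin are preserved exactly; label volumes are written with
#' an integer datatype.
#'
#' @param volume A [cbct_volume()] or [cbct_labels()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  check_volume(volume)
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    cbct_abort(paste0("unsupported output format (need .nii/.nii.gz): ",
                      path), "unsupported_format")
  is_labels <- inherits(volume, "cbct_labels")
  arr <- volume$values
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr,
                         datatype = if (is_labels) "int32" else "double")
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e)
             cbct_abort(paste0("failed to write ", path, ": ",
                               conditionMessage(e)), "io_failure"))
  invisible(path)
}
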