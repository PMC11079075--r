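#' 3D scalar volume with physical spacing
#'
#' A `cbct_volume` is a 3D numeric array together with its voxel spacing (mm
#' per axis) and physical origin. Array axes are indexed `[i, j, k]` in
#' column-major order; `i` is the fastest-varying index. The voxel centre of
#' `values[i, j, k]` sits at `origin + (c(i, j, k) - 1) * spacing` in mm.
#' All index-space operations in the package (cropping, flipping, masking,
#' surface extraction) are documented against this convention.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm per axis (all > 0).
#' @param origin Numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `cbct_volume`.
#' @examples
#' v <- cbct_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(0.4, 0.4, 0.4))
#' dim(v)
#' @export
cbct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as_volume_array(values)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    cbct_abort("`spacing` must be 3 positive finite values (mm).", "bad_spacing")
  if (length(origin) != 3 || any(!is.finite(origin)))
    cbct_abort("`origin` must be 3 finite values (mm).", "bad_origin")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "cbct_volume")
}

#' Integer label volume on the same grid contract as [cbct_volume()]
#'
#' Label semantics follow the dental segmentation convention: 0 background,
#' 1 maxillary bone, 2 mandibular bone, 3 maxillary sinus, 4 mandibular
#' canal, and 11-48 individual teeth by FDI two-digit notation.
#'
#' @inheritParams cbct_volume
#' @param values 3D array of integer-valued labels.
#' @return An object of class `cbct_labels` (also a `cbct_volume`).
#' @export
cbct_labels <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as_volume_array(values)
  if (any(values != round(values)))
    cbct_abort("label values must be integer-valued.", "non_integer_labels")
  storage.mode(values) <- "integer"
  out <- cbct_volume(values, spacing, origin)
  class(out) <- c("cbct_labels", class(out))
  out
}

as_volume_array <- function(values) {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) != 3)
    cbct_abort("`values` must be a 3D array.", "bad_dims")
  if (any(dim(values) < 1))
    cbct_abort("grid dimensions must all be >= 1.", "bad_dims")
  values
}

#' @export
dim.cbct_volume <- function(x) dim(x$values)

#' @export
print.cbct_volume <- function(x, ...) {
  kind <- if (inherits(x, "cbct_labels")) "cbct_labels" else "cbct_volume"
  cat(sprintf("<%s> %s voxels @ %s mm\n", kind,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x")))
  if (inherits(x, "cbct_labels")) {
    labs <- sort(unique(as.vector(x$values)))
    cat("  labels:", paste(utils::head(labs, 12), collapse = ", "),
        if (length(labs) > 12) "..." else "", "\n")
  } else {
    rng <- range(x$values)
    cat(sprintf("  gray range: [%.6g, %.6g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
as.array.cbct_volume <- function(x, ...) x$values

# shared precondition: two volumes live on the same grid
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    cbct_abort(sprintf("%s have mismatched grid dimensions (%s vs %s).", what,
                       paste(dim(a$values), collapse = "x"),
                       paste(dim(b$values), collapse = "x")),
               "grid_mismatch")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    cbct_abort(sprintf("%s have mismatched voxel spacing.", what),
               "grid_mismatch")
  invisible(TRUE)
}

check_volume <- function(volume, arg = "volume") {
  if (!inherits(volume, "cbct_volume"))
    cbct_abort(sprintf("`%s` must be a cbct_volume (see cbct_volume()).", arg),
               "bad_input")
  invisible(TRUE)
}
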