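#' Training-augmentation configuration
#'
#' Defaults reproduce the standard training recipe: random 96 x 160 x 160
#' crops, independent mirror flips along the three axes, and 0-16 randomly
#' placed 12 x 12 x 12 zero cubes (cutout).
#'
#' @param crop_shape Integer length-3 crop size in voxels
#'   (default `c(96, 160, 160)`).
#' @param mask_cube Cutout cube edge length in voxels (default 12).
#' @param mask_count_range Inclusive integer range for the number of cutout
#'   cubes (default `c(0, 16)`).
#' @param flip_prob_per_axis Probability of mirroring each axis
#'   (default 0.5).
#' @param seed Integer seed documenting the whole transform.
#' @return An `augment_config` list.
#' @export
augment_config <- function(crop_shape = c(96, 160, 160), mask_cube = 12,
                           mask_count_range = c(0, 16),
                           flip_prob_per_axis = 0.5, seed = 1) {
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3 || any(crop_shape < 1))
    cbct_abort("`crop_shape` must be 3 integers >= 1.", "bad_config")
  if (mask_cube < 1)
    cbct_abort("`mask_cube` must be >= 1.", "bad_config")
  mask_count_range <- as.integer(mask_count_range)
  if (length(mask_count_range) != 2 || mask_count_range[1] < 0 ||
      mask_count_range[1] > mask_count_range[2])
    cbct_abort("`mask_count_range` must satisfy 0 <= min <= max.",
               "bad_config")
  if (flip_prob_per_axis < 0 || flip_prob_per_axis > 1)
    cbct_abort("`flip_prob_per_axis` must be in [0, 1].", "bad_config")
  structure(list(crop_shape = crop_shape, mask_cube = as.integer(mask_cube),
                 mask_count_range = mask_count_range,
                 flip_prob_per_axis = flip_prob_per_axis,
                 seed = as.integer(seed)),
            class = "augment_config")
}

pad_to_shape <- function(arr, shape, fill) {
  d <- dim(arr)
  need <- pmax(shape - d, 0L)
  if (all(need == 0L)) return(arr)
  before <- need %/% 2L
  out_dim <- pmax(d, shape)
  out <- array(fill, out_dim)
  out[before[1] + seq_len(d[1]),
      before[2] + seq_len(d[2]),
      before[3] + seq_len(d[3])] <- arr
  out
}

#' Random spatial crop of a volume/label pair
#'
#' Draws a uniformly random fully-in-bounds window of size `shape` and
#' applies the identical window to the image and the labels. Inputs smaller
#' than `shape` are first symmetrically padded (image with its minimum
#' value, labels with background 0), so desk-scale volumes remain usable.
#' Consumes the current RNG stream; call inside [withr::with_seed()] or via
#' [augment_case()] for reproducibility.
#'
#' @param volume A [cbct_volume()].
#' @param labels A [cbct_labels()] on the same grid, or `NULL`.
#' @param shape Integer length-3 crop size (default `c(96, 160, 160)`).
#' @return List with elements `volume` and `labels` (the latter `NULL` if not
#'   supplied), plus attribute `corner` (window start, post-padding indices).
#' @export
random_crop <- function(volume, labels = NULL, shape = c(96, 160, 160)) {
  check_volume(volume)
  shape <- as.integer(shape)
  if (!is.null(labels)) check_same_grid(volume, labels, "volume and labels")
  arr <- pad_to_shape(volume$values, shape, fill = min(volume$values))
  lab <- if (!is.null(labels))
    pad_to_shape(labels$values, shape, fill = 0L)
  d <- dim(arr)
  corner <- vapply(1:3, function(ax) {
    if (d[ax] == shape[ax]) 1L else sample.int(d[ax] - shape[ax] + 1L, 1L)
  }, integer(1))
  ix <- corner[1] + seq_len(shape[1]) - 1L
  iy <- corner[2] + seq_len(shape[2]) - 1L
  iz <- corner[3] + seq_len(shape[3]) - 1L
  sp <- volume$spacing
  out <- list(
    volume = cbct_volume(arr[ix, iy, iz, drop = FALSE], spacing = sp,
                         origin = volume$origin + (corner - 1) * sp),
    labels = if (!is.null(labels))
      cbct_labels(lab[ix, iy, iz, drop = FALSE], spacing = sp,
                  origin = volume$origin + (corner - 1) * sp))
  attr(out, "corner") <- corner
  out
}

flip_array <- function(arr, axes) {
  if (axes[1]) arr <- arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
  if (axes[2]) arr <- arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
  if (axes[3]) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
  arr
}

#' Random three-axis mirror flip
#'
#' Each axis is mirrored independently with probability `prob`; the same
#' axes are applied to the labels, so the voxel multiset of both is
#' preserved. Consumes the current RNG stream.
#'
#' @param volume A [cbct_volume()].
#' @param labels A [cbct_labels()] on the same grid, or `NULL`.
#' @param prob Per-axis flip probability (default 0.5).
#' @param axes Optional logical length-3 forcing the flip decision per axis
#'   (bypasses randomness; used for testing involution).
#' @return List with `volume`, `labels` and attribute `axes` (the draws).
#' @export
random_flip <- function(volume, labels = NULL, prob = 0.5, axes = NULL) {
  check_volume(volume)
  if (!is.null(labels)) check_same_grid(volume, labels, "volume and labels")
  if (is.null(axes)) axes <- stats::runif(3) < prob
  out <- list(
    volume = cbct_volume(flip_array(volume$values, axes),
                         spacing = volume$spacing, origin = volume$origin),
    labels = if (!is.null(labels))
      cbct_labels(flip_array(labels$values, axes),
                  spacing = labels$spacing, origin = labels$origin))
  attr(out, "axes") <- axes
  out
}

#' Random cutout masking (zeroed cubes)
#'
#' Draws `n ~ Uniform{count_min..count_max}` cubes of edge `cube` voxels at
#' uniformly random in-bounds corners (overlaps allowed) and sets the image
#' values inside them to 0. Labels are never touched. Consumes the current
#' RNG stream.
#'
#' @param volume A [cbct_volume()].
#' @param cube Cube edge length in voxels (default 12).
#' @param count_range Inclusive integer range for the cube count
#'   (default `c(0, 16)`).
#' @param n Optional forced cube count (bypasses the draw; for testing).
#' @return A [cbct_volume()] with attribute `n_cubes`.
#' @export
random_mask <- function(volume, cube = 12, count_range = c(0, 16), n = NULL) {
  check_volume(volume)
  cube <- as.integer(cube)
  d <- dim(volume$values)
  if (any(d < cube))
    cbct_abort(sprintf("volume (%s) is smaller than the %d-voxel mask cube.",
                       paste(d, collapse = "x"), cube), "volume_too_small")
  if (is.null(n)) {
    cr <- as.integer(count_range)
    n <- cr[1] + sample.int(cr[2] - cr[1] + 1L, 1L) - 1L
  }
  arr <- volume$values
  for (m in seq_len(n)) {
    corner <- vapply(1:3, function(ax) sample.int(d[ax] - cube + 1L, 1L),
                     integer(1))
    arr[corner[1] + seq_len(cube) - 1L,
        corner[2] + seq_len(cube) - 1L,
        corner[3] + seq_len(cube) - 1L] <- 0
  }
  out <- cbct_volume(arr, spacing = volume$spacing, origin = volume$origin)
  attr(out, "n_cubes") <- n
  out
}

#' Full augmentation pipeline for one training sample
#'
#' Applies crop, flip and cutout masking in that fixed order, drawing all
#' randomness from one stream seeded with `config$seed`, so the seed
#' documents the whole transform and repeated calls are bit-identical.
#'
#' @param volume A [cbct_volume()].
#' @param labels A [cbct_labels()] on the same grid, or `NULL`.
#' @param config An [augment_config()].
#' @return List with `volume` and `labels`.
#' @export
augment_case <- function(volume, labels = NULL, config = augment_config()) {
  withr::with_seed(config$seed, {
    cr <- random_crop(volume, labels, shape = config$crop_shape)
    fl <- random_flip(cr$volume, cr$labels, prob = config$flip_prob_per_axis)
    vol <- random_mask(fl$volume, cube = config$mask_cube,
                       count_range = config$mask_count_range)
    list(volume = vol, labels = fl$labels)
  })
}
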