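#' Preprocessing configuration
#'
#' @param target_spacing Isotropic target voxel spacing in mm (default 0.4).
#' @param upper_percentile Upper clipping percentile in percent
#'   (default 99.5).
#' @param mode `"adaptive"` (histogram-driven bone threshold as the lower
#'   clip) or `"percentile"` (generic baseline: clip to the
#'   `baseline_lower_percentile` / `upper_percentile` window).
#' @param baseline_lower_percentile Lower percentile of the baseline path,
#'   in percent (default 0.5).
#' @param sigma_factor Multiplier for the fitted sigma in adaptive mode
#'   (default 3).
#' @param bin_width Histogram bin width for adaptive mode (default 1).
#' @param peak_params A [peak_search_params()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = 0.4,
                              upper_percentile = 99.5,
                              mode = c("adaptive", "percentile"),
                              baseline_lower_percentile = 0.5,
                              sigma_factor = 3,
                              bin_width = 1,
                              peak_params = peak_search_params()) {
  mode <- match.arg(mode)
  if (target_spacing <= 0)
    cbct_abort("`target_spacing` must be positive (mm).", "bad_config")
  if (!(baseline_lower_percentile > 0 &&
        baseline_lower_percentile < upper_percentile &&
        upper_percentile < 100))
    cbct_abort("need 0 < baseline_lower_percentile < upper_percentile < 100.",
               "bad_config")
  structure(list(target_spacing = target_spacing,
                 upper_percentile = upper_percentile,
                 mode = mode,
                 baseline_lower_percentile = baseline_lower_percentile,
                 sigma_factor = sigma_factor,
                 bin_width = bin_width,
                 peak_params = peak_params),
            class = "preprocess_config")
}

# 1-D interpolation of `arr` along `axis` onto n_out evenly spaced samples
# with the voxel-centre convention (sample i' sits at source index
# (i'-1) * target_spacing / src_spacing + 1).
interp_axis <- function(arr, axis, src_spacing, target_spacing, n_out,
                        method) {
  n_in <- dim(arr)[axis]
  pos <- (seq_len(n_out) - 1) * target_spacing / src_spacing + 1
  pos <- pmin(pmax(pos, 1), n_in)
  ord <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, ord)
  dn <- dim(ap)
  if (method == "nearest" || n_in == 1) {
    idx <- pmin(pmax(round(pos), 1), n_in)
    out <- ap[idx, , , drop = FALSE]
  } else {
    i0 <- pmin(floor(pos), n_in - 1)
    i0 <- pmax(i0, 1)
    w <- pos - i0
    # recycling along the fastest (first) dimension applies weight w[i']
    out <- ap[i0, , , drop = FALSE] * (1 - w) +
      ap[i0 + 1, , , drop = FALSE] * w
  }
  aperm(out, order(ord))
}

#' Resample a volume to isotropic voxel spacing
#'
#' Separable per-axis interpolation onto a grid with the requested isotropic
#' spacing. Output dimensions are `round(dim * spacing / target)` (at least
#' 1), which preserves the physical extent to within one voxel. Images use
#' trilinear interpolation; label volumes must use nearest-neighbour so that
#' no new label values are invented.
#'
#' @param volume A [cbct_volume()] or [cbct_labels()].
#' @param target_spacing Target spacing in mm (default 0.4).
#' @param interpolation `"linear"` or `"nearest"`. Defaults to `"nearest"`
#'   for label volumes and `"linear"` otherwise.
#' @return A resampled volume of the same class.
#' @export
resample_isotropic <- function(volume, target_spacing = 0.4,
                               interpolation = NULL) {
  check_volume(volume)
  is_labels <- inherits(volume, "cbct_labels")
  interpolation <- interpolation %||% (if (is_labels) "nearest" else "linear")
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (is_labels && interpolation != "nearest")
    cbct_abort("label volumes must be resampled with nearest interpolation.",
               "bad_interpolation")
  if (target_spacing <= 0)
    cbct_abort("`target_spacing` must be positive (mm).", "bad_config")

  d_in <- dim(volume$values)
  n_out <- pmax(1L, as.integer(round(d_in * volume$spacing / target_spacing)))
  arr <- volume$values
  if (is_labels) storage.mode(arr) <- "double"
  for (ax in 1:3) {
    if (n_out[ax] == d_in[ax] && isTRUE(all.equal(volume$spacing[ax],
                                                  target_spacing)))
      next
    arr <- interp_axis(arr, ax, volume$spacing[ax], target_spacing,
                       n_out[ax], interpolation)
  }
  if (is_labels)
    cbct_labels(arr, spacing = rep(target_spacing, 3), origin = volume$origin)
  else
    cbct_volume(arr, spacing = rep(target_spacing, 3), origin = volume$origin)
}

#' Clip to an intensity window and z-normalize
#'
#' Clamps gray values to `[lower, P_upper]` where `P_upper` is the
#' `upper_percentile` gray value of the volume (computed on the unclipped
#' values, linear interpolation between order statistics), then shifts and
#' scales linearly so the whole volume has mean 0 and population standard
#' deviation 1. Clamping precedes normalization; out-of-window voxels are
#' clamped, not removed, so the grid geometry is preserved.
#'
#' @param volume A [cbct_volume()].
#' @param lower Lower clamp in gray-value units (e.g. the bone threshold
#'   `x_b`, or a baseline percentile value).
#' @param upper_percentile Upper percentile in percent (default 99.5).
#' @return A normalized [cbct_volume()] with attributes `clip_lower` and
#'   `clip_upper` recording the window used.
#' @export
clip_normalize <- function(volume, lower, upper_percentile = 99.5) {
  check_volume(volume)
  v <- volume$values
  upper <- as.numeric(stats::quantile(v, upper_percentile / 100,
                                      names = FALSE, type = 7))
  if (!(lower < upper))
    cbct_abort(sprintf(
      "lower clamp (%g) must be below the upper percentile value (%g).",
      lower, upper), "bad_clip_window")
  v <- pmin(pmax(v, lower), upper)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0)
    cbct_abort("volume has zero variance after clamping (degenerate).",
               "zero_variance")
  out <- volume
  out$values <- (v - m) / s
  attr(out, "clip_lower") <- lower
  attr(out, "clip_upper") <- upper
  out
}

#' Full preprocessing chain for one scan
#'
#' Standardizes a CBCT volume for network training or inference: resample to
#' isotropic `target_spacing`, derive the lower clipping bound (adaptive
#' bone threshold, or the baseline lower percentile), clamp to
#' `[lower, P_upper]`, and z-normalize to mean 0 / sd 1. In adaptive mode a
#' histogram with no qualifying soft-tissue peak (or a failed Gaussian fit)
#' triggers the percentile baseline with a warning, so batch runs never
#' abort on one pathological scan.
#'
#' @param volume A [cbct_volume()].
#' @param config A [preprocess_config()].
#' @return A `cbct_preprocessed` list: `volume` (the standardized image),
#'   `threshold` (a `threshold_result`, or `NULL` when the percentile path
#'   ran) and `provenance` (mode requested/used, clip window, grid before
#'   and after).
#' @examples
#' ph <- generate_phantom(phantom_config(dims = c(48, 48, 40), seed = 1))
#' pp <- preprocess_case(ph$volume, preprocess_config(target_spacing = 0.4))
#' c(mean(pp$volume$values), sd(pp$volume$values))
#' @export
preprocess_case <- function(volume, config = preprocess_config()) {
  check_volume(volume)
  dims_in <- dim(volume$values)
  spacing_in <- volume$spacing
  res <- resample_isotropic(volume, config$target_spacing, "linear")

  threshold <- NULL
  mode_used <- config$mode
  if (config$mode == "adaptive") {
    threshold <- tryCatch(
      adaptive_threshold(res, params = config$peak_params,
                         sigma_factor = config$sigma_factor,
                         bin_width = config$bin_width),
      cbctools_error = function(e) {
        warning(sprintf(
          "adaptive thresholding failed (%s); falling back to percentile baseline.",
          e$reason), call. = FALSE)
        NULL
      })
    if (is.null(threshold)) mode_used <- "percentile"
  }
  lower <- if (mode_used == "adaptive") threshold$x_b else
    as.numeric(stats::quantile(res$values,
                               config$baseline_lower_percentile / 100,
                               names = FALSE, type = 7))
  norm <- clip_normalize(res, lower, config$upper_percentile)

  structure(list(
    volume = norm,
    threshold = threshold,
    provenance = list(
      mode_requested = config$mode,
      mode_used = mode_used,
      target_spacing = config$target_spacing,
      input_dims = dims_in,
      input_spacing = spacing_in,
      output_dims = dim(norm$values),
      clip_lower = attr(norm, "clip_lower"),
      clip_upper = attr(norm, "clip_upper"),
      sigma_factor = config$sigma_factor,
      upper_percentile = config$upper_percentile,
      baseline_lower_percentile = config$baseline_lower_percentile)),
    class = "cbct_preprocessed")
}

#' @export
print.cbct_preprocessed <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<cbct_preprocessed> %s -> %s @ %g mm, mode %s, window [%.2f, %.2f]\n",
              paste(p$input_dims, collapse = "x"),
              paste(p$output_dims, collapse = "x"),
              p$target_spacing, p$mode_used, p$clip_lower, p$clip_upper))
  invisible(x)
}

#' One-row provenance summary of a preprocessed case
#' @param x A `cbct_preprocessed`.
#' @param ... Unused.
#' @export
glance.cbct_preprocessed <- function(x, ...) {
  p <- x$provenance
  tibble::tibble(mode_requested = p$mode_requested, mode_used = p$mode_used,
                 target_spacing = p$target_spacing,
                 clip_lower = p$clip_lower, clip_upper = p$clip_upper,
                 x_b = if (is.null(x$threshold)) NA_real_ else x$threshold$x_b,
                 sigma = if (is.null(x$threshold)) NA_real_ else
                   x$threshold$fit$sigma)
}
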