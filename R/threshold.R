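#' Bone truncation threshold from a fitted soft-tissue peak
#'
#' The adaptive preprocessing removes gray values below bone via
#' \eqn{x_b = x_s + d}, where \eqn{x_s} is the soft-tissue gray value (the
#' fitted peak mean by default) and the soft-tissue/bone gap \eqn{d} is tied
#' to the fitted peak width as \eqn{d = \code{sigma\_factor} \times \sigma}.
#' The default factor 3 is the calibration that maximizes downstream
#' segmentation accuracy.
#'
#' @param fit A `gaussian_peak_fit`.
#' @param sigma_factor Non-negative multiplier relating `d` to the fitted
#'   sigma (default 3).
#' @param x_s Soft-tissue gray value; defaults to the fitted mean `fit$mu`.
#'   Pass the raw filtered-curve peak midpoint to use the un-fitted variant.
#' @return A `threshold_result`: list with `x_s`, `d`, `x_b`
#'   (`x_b == x_s + d` exactly), `sigma_factor` and `fit`.
#' @export
compute_threshold <- function(fit, sigma_factor = 3, x_s = fit$mu) {
  if (!inherits(fit, "gaussian_peak_fit"))
    cbct_abort("`fit` must be a gaussian_peak_fit.", "bad_input")
  if (!is.numeric(sigma_factor) || length(sigma_factor) != 1 ||
      sigma_factor < 0)
    cbct_abort("`sigma_factor` must be a single non-negative number.",
               "bad_sigma_factor")
  d <- sigma_factor * fit$sigma
  structure(list(x_s = x_s, d = d, x_b = x_s + d,
                 sigma_factor = sigma_factor, fit = fit),
            class = "threshold_result")
}

#' Adaptive bone threshold of a CBCT volume
#'
#' Full histogram-driven flow: bin the gray values, median-filter the
#' histogram to suppress air / outside-field-of-view spikes, locate the
#' soft-tissue peak, fit a Gaussian in a window around it, and derive the
#' bone truncation value \eqn{x_b = x_s + sigma\_factor \cdot \sigma}.
#' Deterministic for a fixed input.
#'
#' @param volume A [cbct_volume()].
#' @param params A [peak_search_params()].
#' @param sigma_factor Multiplier for the fitted sigma (default 3).
#' @param bin_width Histogram bin width in gray units (default 1).
#' @param x_s_source `"fitted"` (default) takes the soft-tissue value from
#'   the fitted Gaussian mean; `"raw"` takes the filtered-curve peak midpoint.
#' @return A `threshold_result` carrying, in addition, the raw and filtered
#'   histograms (`histogram`, `smoothed`) and the detected `peak_center` for
#'   diagnostics and plotting.
#' @section Errors: propagates `cbctools_error_no_peak` and
#'   `cbctools_error_fit_failure`; both carry a machine-readable `reason`
#'   field so batch callers can fall back to percentile preprocessing.
#' @examples
#' ph <- generate_phantom(phantom_config(dims = c(48, 48, 40), seed = 1))
#' thr <- adaptive_threshold(ph$volume)
#' thr$x_b
#' @export
adaptive_threshold <- function(volume, params = peak_search_params(),
                               sigma_factor = 3, bin_width = 1,
                               x_s_source = c("fitted", "raw")) {
  x_s_source <- match.arg(x_s_source)
  hist <- compute_histogram(volume, bin_width = bin_width)
  # degenerate histograms narrower than the filter window: shrink the
  # kernel to the largest odd length that fits, so near-constant volumes
  # fall through to the no-peak error rather than a kernel error
  n_bins <- length(hist$counts)
  kernel <- min(params$median_kernel, n_bins - (1 - n_bins %% 2))
  smoothed <- smooth_histogram(hist, kernel = kernel)
  peak <- detect_soft_tissue_peak(smoothed, params)
  fit <- fit_gaussian(smoothed, as.numeric(peak), params$roi_halfwidth)
  x_s <- if (x_s_source == "fitted") fit$mu else as.numeric(peak)
  out <- compute_threshold(fit, sigma_factor, x_s = x_s)
  out$histogram <- hist
  out$smoothed <- smoothed
  out$peak_center <- as.numeric(peak)
  out$x_s_source <- x_s_source
  out$bin_width <- bin_width
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> x_s = %.2f, d = %.2f (%g x sigma), x_b = %.2f\n",
              x$x_s, x$d, x$sigma_factor, x$x_b))
  invisible(x)
}

#' Tidy a threshold result
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return One-row tibble with `x_s`, `d`, `x_b`, `sigma_factor`, `mu`,
#'   `sigma`, `amplitude` and `rms_residual` (the JSON sidecar schema).
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble::tibble(x_s = x$x_s, d = x$d, x_b = x$x_b,
                 sigma_factor = x$sigma_factor,
                 mu = x$fit$mu, sigma = x$fit$sigma,
                 amplitude = x$fit$amplitude,
                 rms_residual = x$fit$rms_residual)
}

#' Diagnostic plot of the adaptive thresholding flow
#'
#' Reproduces the standard diagnostic: original histogram (blue), median
#' filtered curve (red), fitted Gaussian (green) and the peak-midpoint /
#' bone-threshold markers.
#'
#' @param object A `threshold_result` from [adaptive_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_result <- function(object, ...) {
  if (is.null(object$histogram))
    cbct_abort("plotting needs a threshold_result from adaptive_threshold().",
               "bad_input")
  df <- dplyr::bind_rows(
    tibble::tibble(gray = object$histogram$bin_centers,
                   count = object$histogram$counts, curve = "original"),
    tibble::tibble(gray = object$smoothed$bin_centers,
                   count = object$smoothed$counts, curve = "filtered"))
  xs <- seq(object$fit$roi_lo, object$fit$roi_hi, length.out = 200)
  gdf <- tibble::tibble(gray = xs, count = predict_gaussian(object$fit, xs),
                        curve = "gaussian fit")
  ggplot2::ggplot(dplyr::bind_rows(df, gdf),
                  ggplot2::aes(x = gray, y = count, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(original = "blue",
                                            filtered = "red",
                                            `gaussian fit` = "darkgreen")) +
    ggplot2::geom_vline(xintercept = object$x_s, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$x_b, linetype = "dotted") +
    ggplot2::labs(x = "gray value", y = "voxel count",
                  title = sprintf("x_s = %.1f, x_b = %.1f (d = %g sigma)",
                                  object$x_s, object$x_b,
                                  object$sigma_factor)) +
    ggplot2::theme_minimal()
}
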