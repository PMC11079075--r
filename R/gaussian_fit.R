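#' Fit a Gaussian density to the soft-tissue peak region
#'
#' Models the histogram counts in a window of `roi_halfwidth` gray units on
#' both sides of the detected peak midpoint with a scaled Gaussian density
#'
#' \deqn{f(x) = \frac{k}{\sqrt{2\pi}\,\sigma}
#'       e^{-\frac{(x-\mu)^2}{2\sigma^2}}}{f(x) = k/(sqrt(2*pi)*sigma) * exp(-(x-mu)^2/(2*sigma^2))}
#'
#' where \eqn{\mu} is the peak midpoint, \eqn{\sigma} the standard deviation
#' and \eqn{k} the amplitude. Parameters minimize the sum of squared
#' residuals over the window (Levenberg-Marquardt, via
#' [minpack.lm::nlsLM()]), initialized at \eqn{\mu_0 =} `center`,
#' \eqn{\sigma_0 =} `roi_halfwidth / 6` and
#' \eqn{k_0 = y(center)\sqrt{2\pi}\sigma_0}, with \eqn{\sigma > 0} enforced.
#'
#' @param hist A `gray_histogram` (normally the median-filtered one).
#' @param center Peak midpoint in gray-value units, e.g. from
#'   [detect_soft_tissue_peak()].
#' @param roi_halfwidth Fitting window half-width in gray-value units
#'   (default 200).
#' @return A `gaussian_peak_fit`: list with `mu`, `sigma`, `amplitude`,
#'   `rms_residual` (counts), `roi_lo`, `roi_hi` and `n_bins`.
#' @section Errors: non-convergence, a degenerate window (< 7 bins), sigma
#'   collapsing to its positivity bound, or a fitted mean escaping the window
#'   signal an error of class `cbctools_error_fit_failure`.
#' @export
fit_gaussian <- function(hist, center, roi_halfwidth = 200) {
  check_histogram(hist)
  roi_lo <- center - roi_halfwidth
  roi_hi <- center + roi_halfwidth
  in_roi <- hist$bin_centers >= roi_lo & hist$bin_centers <= roi_hi
  if (sum(in_roi) < 7)
    cbct_abort(sprintf(
      "fitting window [%g, %g] covers only %d histogram bins (need >= 7).",
      roi_lo, roi_hi, sum(in_roi)), "fit_failure")
  x <- hist$bin_centers[in_roi]
  y <- hist$counts[in_roi]

  sigma0 <- roi_halfwidth / 6
  y_center <- y[which.min(abs(x - center))]
  k0 <- max(y_center, 1) * sqrt(2 * pi) * sigma0
  sigma_floor <- 1e-6

  run_lm <- function(start) {
    # the LM Jacobian uses relative finite-difference steps, so a start of
    # exactly 0 produces a zero derivative column; nudge it off zero
    if (abs(start$mu) < 1e-8) start$mu <- 1e-3
    minpack.lm::nlsLM(
      y ~ k / (sqrt(2 * pi) * sigma) * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = data.frame(x = x, y = y),
      start = start,
      lower = c(mu = -Inf, sigma = sigma_floor, k = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  # fallback start from moments of the window, used when the default start
  # sits on a degenerate point of the numeric Jacobian
  w <- pmax(y, 0) / max(sum(pmax(y, 0)), 1e-12)
  mu_m <- sum(w * x)
  sigma_m <- max(sqrt(sum(w * (x - mu_m)^2)), 1)
  k_m <- max(sum(y) * (x[2] - x[1]), 1e-6)
  fit <- tryCatch(
    run_lm(list(mu = center, sigma = sigma0, k = k0)),
    error = function(e1) {
      tryCatch(run_lm(list(mu = mu_m, sigma = sigma_m, k = k_m)),
               error = function(e2) {
                 cbct_abort(paste0("Gaussian peak fit did not converge: ",
                                   conditionMessage(e2)), "fit_failure")
               })
    })

  est <- stats::coef(fit)
  if (est[["sigma"]] <= 2 * sigma_floor)
    cbct_abort("Gaussian peak fit collapsed (sigma at positivity bound).",
               "fit_failure")
  if (est[["mu"]] <= roi_lo || est[["mu"]] >= roi_hi)
    cbct_abort("fitted peak mean fell outside the fitting window.",
               "fit_failure")

  structure(list(mu = unname(est[["mu"]]),
                 sigma = unname(est[["sigma"]]),
                 amplitude = unname(est[["k"]]),
                 rms_residual = sqrt(mean(stats::resid(fit)^2)),
                 roi_lo = roi_lo, roi_hi = roi_hi,
                 n_bins = length(x)),
            class = "gaussian_peak_fit")
}

#' Evaluate the fitted Gaussian model at gray values `x`
#' @param fit A `gaussian_peak_fit`.
#' @param x Gray values.
#' @return Model counts.
#' @export
predict_gaussian <- function(fit, x) {
  fit$amplitude / (sqrt(2 * pi) * fit$sigma) *
    exp(-(x - fit$mu)^2 / (2 * fit$sigma^2))
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  cat(sprintf("<gaussian_peak_fit> mu = %.2f, sigma = %.2f, k = %.4g (rms %.3g over %d bins)\n",
              x$mu, x$sigma, x$amplitude, x$rms_residual, x$n_bins))
  invisible(x)
}

#' Tidy a Gaussian peak fit into a one-row-per-parameter tibble
#' @param x A `gaussian_peak_fit`.
#' @param ... Unused.
#' @export
tidy.gaussian_peak_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "amplitude"),
                 estimate = c(x$mu, x$sigma, x$amplitude))
}

#' One-row fit summary
#' @param x A `gaussian_peak_fit`.
#' @param ... Unused.
#' @export
glance.gaussian_peak_fit <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual, n_bins = x$n_bins,
                 roi_lo = x$roi_lo, roi_hi = x$roi_hi)
}

#' Turn a fitted object into a tidy tibble
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
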