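#' Gray-value histogram of a volume
#'
#' Bins the voxel gray values of a volume into a uniformly spaced frequency
#' curve. The histogram is the signal on which the adaptive preprocessing
#' operates: CBCT gray histograms typically show one or two narrow spikes
#' (air and outside-field-of-view voxels, which share a single value) and one
#' broad peak from soft tissue, while bone and teeth form no distinct mode.
#'
#' @param volume A [cbct_volume()].
#' @param bin_width Bin width in gray-value units (default 1).
#' @return A `gray_histogram`: list with `bin_centers`, `counts`, `bin_width`
#'   and `total_voxels`. `sum(counts) == total_voxels` always holds and bins
#'   span the full value range of the volume.
#' @seealso [smooth_histogram()], [detect_soft_tissue_peak()]
#' @export
compute_histogram <- function(volume, bin_width = 1) {
  check_volume(volume)
  v <- as.vector(volume$values)
  if (length(v) == 0)
    cbct_abort("volume is empty.", "empty_volume")
  n_bad <- sum(!is.finite(v))
  if (n_bad > 0)
    cbct_abort(sprintf("volume contains %d non-finite voxel value(s).", n_bad),
               "non_finite_values")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    cbct_abort("`bin_width` must be a single positive number.", "bad_bin_width")

  vmin <- min(v)
  vmax <- max(v)
  n_bins <- floor((vmax - vmin) / bin_width) + 1L
  idx <- floor((v - vmin) / bin_width + 0.5) + 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  new_gray_histogram(bin_centers = vmin + (seq_len(n_bins) - 1) * bin_width,
                     counts = counts, bin_width = bin_width,
                     total_voxels = length(v))
}

new_gray_histogram <- function(bin_centers, counts, bin_width, total_voxels) {
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts),
                 bin_width = bin_width,
                 total_voxels = total_voxels),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> %d bins of width %g, %d voxels, support [%g, %g]\n",
              length(x$counts), x$bin_width, x$total_voxels,
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' @export
as_tibble.gray_histogram <- function(x, ...) {
  tibble::tibble(gray = x$bin_centers, count = x$counts)
}

#' Median-filter a gray histogram
#'
#' Treats the histogram as a 1-D signal and replaces each count by the median
#' of its `kernel`-wide neighbourhood (edges handled by symmetric
#' reflection). This removes the single-bin air / outside-field-of-view
#' spikes without eroding the broad soft-tissue peak.
#'
#' @param hist A `gray_histogram`.
#' @param kernel Odd window length in bins (default 5).
#' @return A `gray_histogram` with the same binning and filtered counts.
#' @export
smooth_histogram <- function(hist, kernel = 5) {
  check_histogram(hist)
  n <- length(hist$counts)
  if (kernel %% 2 == 0)
    cbct_abort("median filter `kernel` must be odd.", "even_kernel")
  if (kernel < 1 || kernel > n)
    cbct_abort("`kernel` must be between 1 and the number of bins.",
               "bad_kernel")
  if (kernel == 1) return(hist)
  h <- (kernel - 1L) / 2L
  padded <- c(rev(hist$counts[seq_len(h)]), hist$counts,
              rev(hist$counts[(n - h + 1):n]))
  sm <- stats::runmed(padded, kernel, endrule = "keep")
  out <- hist
  out$counts <- as.numeric(sm[(h + 1):(h + n)])
  # the median filter redistributes counts, so conservation is not claimed
  out$total_voxels <- hist$total_voxels
  out
}

check_histogram <- function(hist) {
  if (!inherits(hist, "gray_histogram"))
    cbct_abort("expected a gray_histogram (see compute_histogram()).",
               "bad_input")
  invisible(TRUE)
}

#' Peak-search parameters for soft-tissue detection
#'
#' @param min_peak_width Minimum peak width at half prominence, in bins
#'   (default 5).
#' @param min_peak_height_fraction Minimum peak height as a fraction of the
#'   total voxel count (default 0.001, i.e. 0.1%).
#' @param roi_halfwidth Half-width of the Gaussian fitting window around the
#'   detected peak, in gray-value units (default 200).
#' @param median_kernel Median-filter window in bins (odd, default 5).
#' @return A `peak_search_params` list.
#' @export
peak_search_params <- function(min_peak_width = 5,
                               min_peak_height_fraction = 0.001,
                               roi_halfwidth = 200,
                               median_kernel = 5) {
  if (min_peak_width < 1)
    cbct_abort("`min_peak_width` must be >= 1 bin.", "bad_params")
  if (min_peak_height_fraction <= 0 || min_peak_height_fraction >= 1)
    cbct_abort("`min_peak_height_fraction` must be in (0, 1).", "bad_params")
  if (roi_halfwidth <= 0)
    cbct_abort("`roi_halfwidth` must be positive.", "bad_params")
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    cbct_abort("`median_kernel` must be odd and >= 1.", "bad_params")
  structure(list(min_peak_width = min_peak_width,
                 min_peak_height_fraction = min_peak_height_fraction,
                 roi_halfwidth = roi_halfwidth,
                 median_kernel = median_kernel),
            class = "peak_search_params")
}

# All strict local maxima of y (plateaus collapse to their first index, so
# equal-height ties resolve toward the lower gray value). Edge bins are not
# maxima. Returns a data.frame with index, height, prominence and width at
# half prominence (in bins, fractional).
find_histogram_peaks <- function(y) {
  n <- length(y)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0)
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))

  prominence <- numeric(length(peaks))
  width <- numeric(length(peaks))
  for (p in seq_along(peaks)) {
    pk <- peaks[p]
    hp <- y[pk]
    # walk left/right to the first strictly higher sample (or the edge);
    # the prominence base is the lower of the two interval minima
    il <- pk
    lmin <- hp
    while (il > 1L && y[il - 1L] <= hp) {
      il <- il - 1L
      lmin <- min(lmin, y[il])
    }
    ir <- pk
    rmin <- hp
    while (ir < n && y[ir + 1L] <= hp) {
      ir <- ir + 1L
      rmin <- min(rmin, y[ir])
    }
    prominence[p] <- hp - max(lmin, rmin)
    level <- hp - 0.5 * prominence[p]
    # interpolated crossings of the half-prominence level on each flank
    a <- pk
    while (a > il && y[a - 1L] >= level) a <- a - 1L
    left_pos <- if (a == 1L || y[a - 1L] >= level) a else
      a - (y[a] - level) / (y[a] - y[a - 1L])
    b <- pk
    while (b < ir && y[b + 1L] >= level) b <- b + 1L
    right_pos <- if (b == n || y[b + 1L] >= level) b else
      b + (y[b] - level) / (y[b] - y[b + 1L])
    width[p] <- right_pos - left_pos
  }
  data.frame(index = peaks, height = y[peaks],
             prominence = prominence, width = width)
}

#' Locate the soft-tissue peak of a (filtered) gray histogram
#'
#' Finds the highest local maximum whose width at half prominence is at
#' least `min_peak_width` bins and whose height reaches
#' `min_peak_height_fraction` of the total voxel count. Ties between
#' equal-height qualifying peaks resolve toward the lower gray value (soft
#' tissue is darker than bone). The returned value is the gray value of the
#' peak's argmax bin.
#'
#' @param hist A `gray_histogram`, already median-filtered.
#' @param params A [peak_search_params()].
#' @return The peak midpoint in gray-value units, with attributes
#'   `bin_index`, `height` and `width_bins`.
#' @section Errors: if no peak qualifies, an error of class
#'   `cbctools_error_no_peak` is signalled; callers may fall back to
#'   percentile-baseline preprocessing.
#' @export
detect_soft_tissue_peak <- function(hist, params = peak_search_params()) {
  check_histogram(hist)
  pk <- find_histogram_peaks(hist$counts)
  min_height <- params$min_peak_height_fraction * hist$total_voxels
  ok <- pk$width >= params$min_peak_width & pk$height >= min_height
  if (!any(ok))
    cbct_abort("no qualifying soft-tissue peak found in the histogram.",
               "no_peak")
  pk <- pk[ok, , drop = FALSE]
  best <- pk[order(-pk$height, pk$index), , drop = FALSE][1, ]
  structure(hist$bin_centers[best$index],
            bin_index = best$index,
            height = best$height,
            width_bins = best$width)
}
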