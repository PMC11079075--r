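# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately use naive formulations (loops, all-pairs distances)
# so they stay independent of the implementation paths they arbitrate.

# wrap a numeric vector as a 1-D cbct_volume (n x 1 x 1 grid)
vec_volume <- function(v, spacing = c(1, 1, 1)) {
  cbct_volume(array(v, c(length(v), 1, 1)), spacing = spacing)
}

# histogram whose counts at integer centers are given exactly
hist_from_counts <- function(centers, counts) {
  cbctools:::new_gray_histogram(bin_centers = centers, counts = counts,
                                bin_width = diff(centers[1:2]),
                                total_voxels = sum(counts))
}

# scaled Gaussian density counts of the soft-tissue peak model
gauss_counts <- function(x, mu, sigma, k) {
  k / (sqrt(2 * pi) * sigma) * exp(-(x - mu)^2 / (2 * sigma^2))
}

# brute-force median filter with symmetric reflection padding
oracle_median_filter <- function(x, kernel) {
  h <- (kernel - 1) / 2
  n <- length(x)
  padded <- c(rev(x[seq_len(h)]), x, rev(x[(n - h + 1):n]))
  vapply(seq_len(n), function(i) median(padded[i:(i + kernel - 1)]),
         numeric(1))
}

# all-pairs surface-distance oracle: directed nearest distances in mm
oracle_surface_dists <- function(mask_a, mask_b, spacing) {
  pa <- extract_surface(mask_a)
  pb <- extract_surface(mask_b)
  pa_mm <- sweep(pa, 2, spacing, `*`)
  pb_mm <- sweep(pb, 2, spacing, `*`)
  # explicit coordinate differences (no |a|^2+|b|^2-2ab cancellation)
  d2 <- outer(pa_mm[, 1], pb_mm[, 1], `-`)^2 +
    outer(pa_mm[, 2], pb_mm[, 2], `-`)^2 +
    outer(pa_mm[, 3], pb_mm[, 3], `-`)^2
  list(a_to_b = sqrt(apply(d2, 1, min)), b_to_a = sqrt(apply(d2, 2, min)))
}

oracle_hd <- function(mask_a, mask_b, spacing) {
  d <- oracle_surface_dists(mask_a, mask_b, spacing)
  max(max(d$a_to_b), max(d$b_to_a))
}

oracle_asd <- function(mask_a, mask_b, spacing) {
  d <- oracle_surface_dists(mask_a, mask_b, spacing)
  mean(c(d$a_to_b, d$b_to_a))
}

# naive per-class loop over the soft Dice terms (same epsilon contract)
oracle_dice_loss <- function(P, G, epsilon = 1e-5) {
  C <- ncol(P)
  total <- 0
  for (j in seq_len(C)) {
    num <- 0; dp <- 0; dg <- 0
    for (i in seq_len(nrow(P))) {
      num <- num + P[i, j] * G[i, j]
      dp <- dp + P[i, j]^2
      dg <- dg + G[i, j]^2
    }
    total <- total + num / (dp + dg + epsilon)
  }
  unname(1 - (2 / C) * total)
}

# random binary mask pair on a small grid, both guaranteed non-empty and
# below a voxel budget
random_mask_pair <- function(seed, dims = c(12, 12, 12), p = 0.08,
                             max_voxels = 1000) {
  set.seed(seed)
  repeat {
    a <- array(runif(prod(dims)) < p, dims)
    b <- array(runif(prod(dims)) < p, dims)
    if (any(a) && any(b) && sum(a) <= max_voxels && sum(b) <= max_voxels)
      return(list(a = a, b = b))
  }
}

# small, fast phantom used across tests
small_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_config(dims = c(48, 48, 40), seed = seed, ...))
}

# uniform random probability matrix with rows summing to 1
random_prob_matrix <- function(n, c, seed) {
  set.seed(seed)
  P <- matrix(runif(n * c), n, c)
  P / rowSums(P)
}
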