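test_that("resampling scales grid dimensions by the spacing ratio", {
  v <- cbct_volume(array(rnorm(40 * 30 * 20), c(40, 30, 20)),
                   spacing = c(0.8, 0.8, 0.8))
  out <- resample_isotropic(v, 0.4)
  expect_equal(dim(out), c(80L, 60L, 40L))
  expect_equal(out$spacing, rep(0.4, 3))

  # identity when already at the target spacing
  v4 <- cbct_volume(array(rnorm(10^3), c(10, 10, 10)), spacing = rep(0.4, 3))
  expect_equal(resample_isotropic(v4, 0.4)$values, v4$values)

  # physical extent is preserved to within one target voxel
  extent_in <- dim(v) * v$spacing
  extent_out <- dim(out) * out$spacing
  expect_true(all(abs(extent_in - extent_out) < 0.4))
})

test_that("label resampling cannot invent labels", {
  set.seed(2)
  lab <- cbct_labels(array(sample(c(0L, 2L, 31L), 8000, TRUE), c(20, 20, 20)),
                     spacing = rep(0.7, 3))
  out <- resample_isotropic(lab, 0.4)
  expect_s3_class(out, "cbct_labels")
  expect_true(all(unique(as.vector(out$values)) %in%
                    unique(as.vector(lab$values))))
  expect_error(resample_isotropic(lab, 0.4, interpolation = "linear"),
               class = "cbctools_error_bad_interpolation")
})

test_that("resampling down and back preserves the mean gray value", {
  ph <- generate_phantom(phantom_config(seed = 21, outside_fov_value = NULL))
  v <- ph$volume  # 0.4 mm, full-size grid (edge effects scale as 1/dim)
  coarse <- resample_isotropic(v, 0.8)
  back <- resample_isotropic(coarse, 0.4)
  expect_equal(dim(back), dim(v))
  expect_lt(abs(mean(back$values) - mean(v$values)) / abs(mean(v$values)),
            0.01)
})

test_that("clip_normalize clamps then standardizes to mean 0, sd 1", {
  v <- vec_volume(c(0, 100, 200, 1000))
  out <- clip_normalize(v, lower = 100, upper_percentile = 100)
  clamped <- c(100, 100, 200, 1000)
  expect_equal(attr(out, "clip_lower"), 100)
  expect_equal(attr(out, "clip_upper"), 1000)
  m <- mean(clamped); s <- sqrt(mean((clamped - m)^2))
  expect_equal(as.vector(out$values), (clamped - m) / s)

  set.seed(1)
  big <- vec_volume(rnorm(10000, 300, 50))
  norm <- clip_normalize(big, lower = 250)
  expect_lt(abs(mean(norm$values)), 1e-6)
  expect_lt(abs(sqrt(mean((norm$values - mean(norm$values))^2)) - 1), 1e-6)

  # renormalizing an already-standard volume is a no-op
  twice <- clip_normalize(norm, lower = -Inf, upper_percentile = 100)
  expect_lt(max(abs(twice$values - norm$values)), 1e-6)

  expect_error(clip_normalize(vec_volume(rep(5, 10)), lower = 4),
               class = "cbctools_error_zero_variance")
})

test_that("preprocess_case composes resample, threshold and normalization", {
  ph <- generate_phantom(phantom_config(dims = c(48, 48, 40), spacing = 0.8,
                                        seed = 31))
  pp <- preprocess_case(ph$volume, preprocess_config(target_spacing = 0.4))
  expect_equal(pp$volume$spacing, rep(0.4, 3))
  expect_equal(dim(pp$volume), c(96L, 96L, 80L))
  expect_lt(abs(mean(pp$volume$values)), 1e-6)
  expect_lt(abs(sqrt(mean((pp$volume$values - mean(pp$volume$values))^2)) - 1),
            1e-6)
  expect_equal(pp$provenance$mode_used, "adaptive")
  expect_equal(pp$provenance$clip_lower, pp$threshold$x_b)
})

test_that("the percentile baseline clips at the stated percentiles", {
  v <- cbct_volume(array(1:1000, c(10, 10, 10)), spacing = rep(0.4, 3))
  pp <- preprocess_case(v, preprocess_config(target_spacing = 0.4,
                                             mode = "percentile"))
  # linear-interpolation percentile oracle on the explicit sequence 1..1000
  expect_equal(pp$provenance$clip_lower,
               as.numeric(quantile(1:1000, 0.005)), tolerance = 1e-12)
  expect_equal(pp$provenance$clip_lower, 5.995, tolerance = 1e-9)
  expect_equal(pp$provenance$clip_upper,
               as.numeric(quantile(1:1000, 0.995)), tolerance = 1e-12)
  expect_equal(pp$provenance$clip_upper, 995.005, tolerance = 1e-9)
  expect_null(pp$threshold)
})

test_that("adaptive clipping removes more sub-soft-tissue mass than baseline", {
  ph <- small_phantom(seed = 41)
  ada <- preprocess_case(ph$volume, preprocess_config(target_spacing = 0.4))
  base <- preprocess_case(ph$volume,
                          preprocess_config(target_spacing = 0.4,
                                            mode = "percentile"))
  at_floor <- function(pp) mean(pp$volume$values == min(pp$volume$values))
  expect_gt(at_floor(ada), at_floor(base))
})

test_that("adaptive mode falls back to the baseline with a warning", {
  set.seed(7)
  # two exact values only: two 1-bin spikes, no qualifying soft-tissue peak
  v <- cbct_volume(array(sample(c(0, 1000), 4000, TRUE), c(20, 20, 10)),
                   spacing = rep(0.4, 3))
  expect_warning(
    pp <- preprocess_case(v, preprocess_config(target_spacing = 0.4)),
    "falling back")
  expect_equal(pp$provenance$mode_requested, "adaptive")
  expect_equal(pp$provenance$mode_used, "percentile")
  expect_null(pp$threshold)
})
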