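make_pair <- function(dims, seed = 1) {
  set.seed(seed)
  v <- cbct_volume(array(rnorm(prod(dims), 100, 10), dims),
                   spacing = rep(0.4, 3))
  l <- cbct_labels(array(sample(c(0L, 1L, 2L, 36L), prod(dims), TRUE,
                                prob = c(0.7, 0.1, 0.1, 0.1)), dims),
                   spacing = rep(0.4, 3))
  list(v = v, l = l)
}

test_that("random crops have the requested shape and a shared window", {
  p <- make_pair(c(120, 170, 170))
  set.seed(3)
  out <- random_crop(p$v, p$l, shape = c(96, 160, 160))
  expect_equal(dim(out$volume), c(96L, 160L, 160L))
  expect_equal(dim(out$labels), c(96L, 160L, 160L))

  # the identical window applies to image and labels: recover it from the
  # corner and compare against direct subsetting
  corner <- attr(out, "corner")
  ix <- corner[1] + 0:95; iy <- corner[2] + 0:159; iz <- corner[3] + 0:159
  expect_equal(out$volume$values, p$v$values[ix, iy, iz])
  expect_equal(out$labels$values, p$l$values[ix, iy, iz])

  # input exactly equal to the shape has a single placement
  q <- make_pair(c(32, 40, 40))
  same <- random_crop(q$v, q$l, shape = c(32, 40, 40))
  expect_equal(same$volume$values, q$v$values)
  expect_equal(same$labels$values, q$l$values)
})

test_that("undersized inputs are padded symmetrically before cropping", {
  p <- make_pair(c(20, 30, 30))
  out <- random_crop(p$v, p$l, shape = c(32, 40, 40))
  expect_equal(dim(out$volume), c(32L, 40L, 40L))
  # image padding uses the minimum, labels pad with background
  expect_equal(min(out$volume$values), min(p$v$values))
  expect_equal(sort(unique(as.vector(out$labels$values)))[1], 0L)
  # per-class voxel counts survive the shared geometric window
  for (k in c(1L, 2L, 36L))
    expect_equal(sum(out$labels$values == k), sum(p$l$values == k))
})

test_that("grid mismatch between volume and labels is rejected", {
  p <- make_pair(c(20, 20, 20))
  bad <- cbct_labels(array(0L, c(10, 20, 20)), spacing = rep(0.4, 3))
  expect_error(random_crop(p$v, bad, shape = c(10, 10, 10)),
               class = "cbctools_error_grid_mismatch")
})

test_that("mirror flips are involutions that preserve the voxel multiset", {
  p <- make_pair(c(24, 20, 16))
  flipped <- random_flip(p$v, p$l, axes = c(TRUE, TRUE, TRUE))
  expect_equal(sort(as.vector(flipped$volume$values)),
               sort(as.vector(p$v$values)))
  twice <- random_flip(flipped$volume, flipped$labels,
                       axes = c(TRUE, TRUE, TRUE))
  expect_equal(twice$volume$values, p$v$values)
  expect_equal(twice$labels$values, p$l$values)

  # an asymmetric marker moves to the opposite corner under a full flip
  m <- p$v
  m$values[1, 1, 1] <- 1e6
  fm <- random_flip(m, axes = c(TRUE, TRUE, TRUE))
  expect_equal(fm$volume$values[24, 20, 16], 1e6)

  # per-class counts equal between volume and labels under the same axes
  for (k in c(1L, 2L, 36L))
    expect_equal(sum(flipped$labels$values == k), sum(p$l$values == k))
})

test_that("cutout masking zeroes bounded cube volumes and spares labels", {
  p <- make_pair(c(40, 40, 40))
  v_pos <- p$v
  v_pos$values <- abs(v_pos$values) + 1  # strictly positive

  expect_equal(random_mask(v_pos, n = 0)$values, v_pos$values)

  set.seed(5)
  masked <- random_mask(v_pos, cube = 12, n = 16)
  n_zero <- sum(masked$values == 0)
  expect_lte(n_zero, 16 * 12^3)
  expect_gte(n_zero, 12^3)  # at least one full cube survives overlap

  one <- random_mask(v_pos, cube = 12, n = 1)
  expect_equal(sum(one$values == 0), 12^3)

  small <- cbct_volume(array(1, c(8, 8, 8)))
  expect_error(random_mask(small, cube = 12),
               class = "cbctools_error_volume_too_small")

  # masking writes only inside the stated cubes: unmasked voxels unchanged
  expect_equal(masked$values[masked$values != 0],
               v_pos$values[masked$values != 0])
})

test_that("the full augmentation pipeline is seed-reproducible", {
  p <- make_pair(c(60, 80, 80))
  cfg <- augment_config(crop_shape = c(48, 64, 64), seed = 17)
  a <- augment_case(p$v, p$l, cfg)
  b <- augment_case(p$v, p$l, cfg)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$labels$values, b$labels$values)
  expect_equal(dim(a$volume), c(48L, 64L, 64L))

  other <- augment_case(p$v, p$l, augment_config(crop_shape = c(48, 64, 64),
                                                 seed = 18))
  expect_false(identical(a$volume$values, other$volume$values))
})
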