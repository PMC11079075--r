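lab_vol <- function(arr, spacing = rep(0.4, 3)) cbct_labels(arr, spacing)

test_that("Dice and IoU match counting on small masks", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2:3, 1, 1] <- 1L
  pa <- lab_vol(a); pb <- lab_vol(b)
  expect_equal(dice_score(pa, pa, 1), 1.0)
  expect_equal(dice_score(pa, pb, 1), 0.5)      # 2*1 / (2+2)
  expect_equal(miou(pa, pb, 1), 1 / 3)          # 1 / (2+2-1)

  disj <- array(0L, c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(dice_score(pa, lab_vol(disj), 1), 0)

  vac <- dice_score(pa, pb, 7)                  # class in neither volume
  expect_equal(as.numeric(vac), 1)
  expect_true(attr(vac, "vacuous"))

  expect_error(miou(pa, pb, class_list = integer(0)),
               class = "cbctools_error_empty_class_list")
  expect_error(dice_score(pa, lab_vol(array(0L, c(3, 4, 4))), 1),
               class = "cbctools_error_grid_mismatch")
})

test_that("mIoU never exceeds mean Dice", {
  for (seed in 1:5) {
    m <- random_mask_pair(seed, dims = c(10, 10, 10), p = 0.2)
    pa <- lab_vol(array(as.integer(m$a), dim(m$a)))
    pb <- lab_vol(array(as.integer(m$b), dim(m$b)))
    expect_lte(miou(pa, pb, 1), as.numeric(dice_score(pa, pb, 1)) + 1e-12)
  }
})

test_that("surface extraction finds six-connected border voxels", {
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(unname(extract_surface(single)), matrix(c(3, 3, 3), 1))

  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(extract_surface(cube)), 26)  # all but the centre

  slab <- array(TRUE, c(6, 6, 1))                # 1-voxel slab: all surface
  expect_equal(nrow(extract_surface(slab)), 36)

  expect_error(extract_surface(array(FALSE, c(3, 3, 3))),
               class = "cbctools_error_empty_mask")
})

test_that("surface distances match hand-computed configurations", {
  a <- array(FALSE, c(10, 4, 4)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(10, 4, 4)); b[7, 2, 2] <- TRUE
  expect_equal(hausdorff_distance(a, b, spacing = rep(0.4, 3)), 2.0)
  expect_equal(hausdorff_distance(a, a, spacing = rep(0.4, 3)), 0)

  # parallel single-voxel-thick planes two voxels apart at 0.25 mm
  p1 <- array(FALSE, c(8, 6, 6)); p1[3, , ] <- TRUE
  p2 <- array(FALSE, c(8, 6, 6)); p2[5, , ] <- TRUE
  expect_equal(average_surface_distance(p1, p2, spacing = rep(0.25, 3)), 0.5)
  expect_equal(average_surface_distance(p1, p1, spacing = rep(0.25, 3)), 0)

  err <- tryCatch(hausdorff_distance(a, array(FALSE, c(10, 4, 4)),
                                     rep(0.4, 3)), error = function(e) e)
  expect_s3_class(err, "cbctools_error_empty_mask")
  expect_match(conditionMessage(err), "gt")
})

test_that("distance metrics agree with the all-pairs oracle", {
  for (seed in 1:20) {
    m <- random_mask_pair(seed)
    spacing <- if (seed %% 2 == 0) c(0.4, 0.4, 0.4) else c(0.3, 0.5, 0.8)
    expect_equal(hausdorff_distance(m$a, m$b, spacing),
                 oracle_hd(m$a, m$b, spacing), tolerance = 1e-9)
    expect_equal(average_surface_distance(m$a, m$b, spacing),
                 oracle_asd(m$a, m$b, spacing), tolerance = 1e-9)
  }
})

test_that("metrics are symmetric and rigid-translation invariant", {
  m <- random_mask_pair(33)
  sp <- c(0.4, 0.4, 0.4)
  expect_equal(hausdorff_distance(m$a, m$b, sp),
               hausdorff_distance(m$b, m$a, sp))
  expect_equal(average_surface_distance(m$a, m$b, sp),
               average_surface_distance(m$b, m$a, sp))
  pa <- lab_vol(array(as.integer(m$a), dim(m$a)))
  pb <- lab_vol(array(as.integer(m$b), dim(m$b)))
  expect_equal(as.numeric(dice_score(pa, pb, 1)),
               as.numeric(dice_score(pb, pa, 1)))
  expect_equal(miou(pa, pb, 1), miou(pb, pa, 1))

  # translate both masks by the same offset inside a larger grid
  shift_into <- function(m, off, dims = c(18, 18, 18)) {
    out <- array(FALSE, dims)
    d <- dim(m)
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
        off[3] + seq_len(d[3])] <- m
    out
  }
  for (off in list(c(0, 0, 0), c(3, 1, 4))) {
    expect_equal(hausdorff_distance(shift_into(m$a, off),
                                    shift_into(m$b, off), sp),
                 hausdorff_distance(m$a, m$b, sp), tolerance = 1e-12)
    expect_equal(average_surface_distance(shift_into(m$a, off),
                                          shift_into(m$b, off), sp),
                 average_surface_distance(m$a, m$b, sp), tolerance = 1e-12)
  }
})

test_that("FDI codes map to tooth positions with quadrants merged", {
  expect_equal(fdi_to_position(36), "T6")
  expect_equal(fdi_to_position(11), "T1")
  expect_equal(fdi_to_position(c(11, 21, 31, 41)), rep("T1", 4))
  expect_equal(fdi_to_position(48), "T8")
  expect_error(fdi_to_position(49), class = "cbctools_error_invalid_fdi")
  expect_error(fdi_to_position(50), class = "cbctools_error_invalid_fdi")
  expect_error(fdi_to_position(19), class = "cbctools_error_invalid_fdi")
  expect_error(fdi_to_position(9), class = "cbctools_error_invalid_fdi")
})

test_that("evaluate_case reports every class with statuses and positions", {
  ph <- small_phantom(seed = 51)
  rep <- evaluate_case(ph$labels, ph$labels)
  expect_true(all(rep$dice == 1))
  expect_true(all(rep$iou == 1))
  expect_true(all(rep$hd_mm == 0))
  expect_true(all(rep$asd_mm == 0))
  expect_true(all(c("maxilla", "mandible", "maxillary_sinus",
                    "mandibular_canal") %in% rep$class_name))
  expect_equal(rep$position[rep$class_id == 36], "T6")

  # drop tooth 36 from the prediction
  pred <- ph$labels
  pred$values[pred$values == 36L] <- 0L
  rep2 <- evaluate_case(pred, ph$labels)
  row36 <- rep2[rep2$class_id == 36, ]
  expect_equal(row36$dice, 0)
  expect_equal(row36$status, "missing_pred")
  expect_true(is.na(row36$hd_mm))

  # class absent from both sides is vacuous when asked for explicitly
  rep3 <- evaluate_case(pred, pred, class_list = c(1, 36))
  expect_equal(rep3$status[rep3$class_id == 36], "vacuous")

  # a one-voxel dilation keeps ASD below one voxel spacing for every class
  dil <- perturb_labels(ph$labels, "dilate", 1)
  rep4 <- evaluate_case(dil, ph$labels)
  expect_true(all(rep4$asd_mm <= 0.4 + 1e-9))

  # a one-voxel rigid shift degrades every class without destroying it
  sh <- perturb_labels(ph$labels, "shift", 1)
  rep5 <- evaluate_case(sh, ph$labels)
  expect_true(all(rep5$dice > 0 & rep5$dice < 1))
  expect_true(all(rep5$hd_mm <= 0.4 + 1e-9))
})

test_that("degradation is monotone under growing perturbations", {
  ph <- small_phantom(seed = 52)
  bone <- ph$labels
  bone$values[!(bone$values %in% c(0L, 2L))] <- 0L  # keep the mandible
  dices <- asds <- numeric(0)
  for (r in 0:2) {
    er <- perturb_labels(bone, "erode", r)
    rep <- evaluate_case(er, bone, class_list = 2)
    dices <- c(dices, rep$dice)
    asds <- c(asds, rep$asd_mm)
  }
  expect_true(all(diff(dices) <= 0))
  expect_true(all(diff(asds) >= 0))
  expect_equal(dices[1], 1)
})

test_that("reports aggregate to mean and sample sd with an Average row", {
  r1 <- evaluate_case(small_phantom(seed = 1)$labels,
                      small_phantom(seed = 1)$labels)
  agg1 <- aggregate_reports(list(r1))
  expect_true(all(agg1$by_class$dice_sd == 0))
  expect_equal(agg1$by_class$class_name[nrow(agg1$by_class)], "Average")
  expect_true(all(c("T1", "T8") %in% agg1$by_position$position))

  # synthetic two-case aggregation: dice 0.9 and 1.0
  mk <- function(d) {
    out <- tibble::tibble(class_id = 2L, class_name = "mandible",
                          position = NA_character_, dice = d, iou = d,
                          hd_mm = 1 - d, asd_mm = 1 - d, n_pred = 10L,
                          n_gt = 10L, status = "ok")
    class(out) <- c("metric_report", class(out))
    out
  }
  agg <- aggregate_reports(list(mk(0.9), mk(1.0)))
  row <- agg$by_class[agg$by_class$class_name == "mandible", ]
  expect_equal(row$dice_mean, 0.95)
  expect_equal(row$dice_sd, 0.0707107, tolerance = 1e-5)
  # column order follows the standard table layout: Dice, mIoU, HD, ASD
  metric_cols <- grep("_(mean|sd)$", names(agg$by_class), value = TRUE)
  expect_equal(metric_cols, c("dice_mean", "dice_sd", "iou_mean", "iou_sd",
                              "hd_mean", "hd_sd", "asd_mean", "asd_sd"))

  expect_error(aggregate_reports(list()),
               class = "cbctools_error_empty_reports")
})
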