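#' Dice similarity coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` between the voxel sets of `class_id` in the
#' prediction and the ground truth. If the class is absent from both
#' volumes the conventional value 1 is returned, flagged with attribute
#' `vacuous = TRUE` (such entries are excluded from aggregates).
#'
#' @param pred,gt [cbct_labels()] on the same grid.
#' @param class_id Integer label value.
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_score <- function(pred, gt, class_id) {
  check_same_grid(pred, gt, "pred and gt")
  a <- pred$values == class_id
  b <- gt$values == class_id
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, vacuous = TRUE))
  2 * sum(a & b) / (na + nb)
}

iou_score <- function(pred, gt, class_id) {
  a <- pred$values == class_id
  b <- gt$values == class_id
  u <- sum(a | b)
  if (u == 0) return(structure(1, vacuous = TRUE))
  sum(a & b) / u
}

#' Mean intersection-over-union across classes
#'
#' Mean over `class_list` of `|A n B| / |A u B|`. Background (0) is excluded
#' by default because including it inflates scores.
#'
#' @param pred,gt [cbct_labels()] on the same grid.
#' @param class_list Classes to average over; default: all non-background
#'   labels present in either volume.
#' @return mIoU fraction in `[0, 1]`.
#' @export
miou <- function(pred, gt, class_list = NULL) {
  check_same_grid(pred, gt, "pred and gt")
  class_list <- class_list %||%
    setdiff(sort(unique(c(pred$values, gt$values))), 0L)
  if (length(class_list) == 0)
    cbct_abort("`class_list` is empty.", "empty_class_list")
  mean(vapply(class_list, function(k) as.numeric(iou_score(pred, gt, k)),
              numeric(1)))
}

#' Surface voxels of a binary mask
#'
#' A mask voxel is a surface voxel if at least one of its six face
#' neighbours is background; the grid boundary counts as background.
#'
#' @param mask 3D logical/0-1 array, or a [cbct_labels()] treated as
#'   `values != 0`.
#' @return Integer `n x 3` matrix of 1-based voxel indices.
#' @export
extract_surface <- function(mask) {
  m <- if (inherits(mask, "cbct_volume")) mask$values != 0 else mask != 0
  if (length(dim(m)) != 3)
    cbct_abort("`mask` must be a 3D array.", "bad_dims")
  if (!any(m))
    cbct_abort("mask is empty; no surface exists.", "empty_mask")
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_bg <- function(ax, dir) {
    # TRUE where the neighbour in direction `dir` along `ax` is foreground
    nb <- array(FALSE, d)
    n <- d[ax]
    if (n == 1) return(nb)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    if (ax == 1) nb[dst, , ] <- m[src, , ]
    if (ax == 2) nb[, dst, ] <- m[, src, ]
    if (ax == 3) nb[, , dst] <- m[, , src]
    nb
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_bg(ax, dir)
  which(m & !interior, arr.ind = TRUE)
}

# Directed nearest-surface distances (mm) in both directions between the
# surfaces of two binary masks, via an exact anisotropic Euclidean distance
# transform cropped to the joint bounding box.
surface_distances <- function(pred_mask, gt_mask, spacing) {
  sp <- extract_surface(pred_mask)
  sg <- extract_surface(gt_mask)
  lo <- pmin(apply(sp, 2, min), apply(sg, 2, min))
  hi <- pmax(apply(sp, 2, max), apply(sg, 2, max))
  dims <- as.integer(hi - lo + 1L)
  lin <- function(idx) {
    (idx[, 1] - lo[1] + 1L) +
      dims[1] * (idx[, 2] - lo[2]) +
      dims[1] * dims[2] * (idx[, 3] - lo[3])
  }
  edt_at <- function(source_idx, query_idx) {
    init <- rep(Inf, prod(dims))
    init[lin(source_idx)] <- 0
    sq <- cpp_sq_edt(init, dims, as.numeric(spacing))
    sqrt(sq[lin(query_idx)])
  }
  list(pred_to_gt = edt_at(sg, sp), gt_to_pred = edt_at(sp, sg))
}

as_binary_mask <- function(x, side) {
  m <- if (inherits(x, "cbct_volume")) x$values != 0 else x != 0
  if (!any(m))
    cbct_abort(sprintf("%s mask is empty.", side), "empty_mask")
  m
}

#' Hausdorff distance between two masks, in mm
#'
#' Maximum over both surfaces of the shortest Euclidean distance to the
#' other surface (the exact maximum, not a percentile), with anisotropic
#' voxel spacing honoured. Distances are measured between surface-voxel
#' centres.
#'
#' @param pred_mask,gt_mask 3D binary arrays (or label volumes treated as
#'   `!= 0`); both non-empty.
#' @param spacing Voxel spacing in mm (length 3).
#' @param percentile Percentile of the pooled directed distances in (0, 100];
#'   100 (default) is the exact Hausdorff distance, 95 gives HD95.
#' @return Distance in mm.
#' @export
hausdorff_distance <- function(pred_mask, gt_mask, spacing,
                               percentile = 100) {
  p <- as_binary_mask(pred_mask, "pred")
  g <- as_binary_mask(gt_mask, "gt")
  d <- surface_distances(p, g, spacing)
  if (percentile >= 100)
    max(max(d$pred_to_gt), max(d$gt_to_pred))
  else
    max(stats::quantile(d$pred_to_gt, percentile / 100, names = FALSE),
        stats::quantile(d$gt_to_pred, percentile / 100, names = FALSE))
}

#' Average (symmetric) surface distance between two masks, in mm
#'
#' Mean of the nearest-surface distances pooled from both directions
#' (prediction surface to truth surface and vice versa).
#'
#' @inheritParams hausdorff_distance
#' @return Distance in mm.
#' @export
average_surface_distance <- function(pred_mask, gt_mask, spacing) {
  p <- as_binary_mask(pred_mask, "pred")
  g <- as_binary_mask(gt_mask, "gt")
  d <- surface_distances(p, g, spacing)
  mean(c(d$pred_to_gt, d$gt_to_pred))
}

#' Tooth position group (T1-T8) of an FDI two-digit code
#'
#' FDI permanent-tooth codes combine a quadrant digit (1-4) with a position
#' digit (1-8: central incisor ... third molar). Quadrants are merged for
#' per-position reporting, so e.g. 11, 21, 31 and 41 all map to `"T1"` and
#' 36 maps to `"T6"`.
#'
#' @param fdi_code Integer vector of FDI codes.
#' @return Character vector `"T1"`..`"T8"`.
#' @export
fdi_to_position <- function(fdi_code) {
  q <- fdi_code %/% 10
  p <- fdi_code %% 10
  bad <- !(q %in% 1:4) | !(p %in% 1:8) | fdi_code != round(fdi_code)
  if (any(bad))
    cbct_abort(sprintf("invalid FDI tooth code(s): %s",
                       paste(unique(fdi_code[bad]), collapse = ", ")),
               "invalid_fdi")
  paste0("T", p)
}

is_fdi <- function(code) {
  q <- code %/% 10
  p <- code %% 10
  q %in% 1:4 & p %in% 1:8
}

structural_class_names <- c(`1` = "maxilla", `2` = "mandible",
                            `3` = "maxillary_sinus", `4` = "mandibular_canal")

#' Evaluate a predicted segmentation against the ground truth
#'
#' Computes Dice, IoU, Hausdorff distance and average surface distance for
#' every structural class (maxilla, mandible, maxillary sinus, mandibular
#' canal) and every FDI-coded tooth present in either volume, grouping teeth
#' into positions T1-T8. A class present in exactly one volume gets Dice and
#' IoU 0 with distances flagged undefined (`NA`, status `missing_pred` /
#' `missing_gt`); a class in `class_list` absent from both is reported with
#' status `vacuous` (Dice 1 by convention) and excluded from aggregates.
#'
#' @param pred,gt [cbct_labels()] on the same grid.
#' @param class_list Optional explicit class set; default: union of
#'   non-background labels present in either volume.
#' @return A `metric_report` tibble with columns `class_id`, `class_name`,
#'   `position`, `dice`, `iou`, `hd_mm`, `asd_mm`, `n_pred`, `n_gt`,
#'   `status`.
#' @examples
#' ph <- generate_phantom(phantom_config(dims = c(48, 48, 40), seed = 1))
#' rep <- evaluate_case(ph$labels, ph$labels)
#' all(rep$dice == 1)
#' @export
evaluate_case <- function(pred, gt, class_list = NULL) {
  check_same_grid(pred, gt, "pred and gt")
  class_list <- class_list %||%
    setdiff(sort(unique(c(pred$values, gt$values))), 0L)
  rows <- purrr::map(class_list, function(k) {
    a <- pred$values == k
    b <- gt$values == k
    na <- sum(a); nb <- sum(b)
    name <- if (as.character(k) %in% names(structural_class_names))
      unname(structural_class_names[as.character(k)])
    else if (is_fdi(k)) paste0("tooth_", k) else paste0("class_", k)
    pos <- if (is_fdi(k)) fdi_to_position(k) else NA_character_
    if (na == 0 && nb == 0) {
      return(tibble::tibble(class_id = k, class_name = name, position = pos,
                            dice = 1, iou = 1, hd_mm = NA_real_,
                            asd_mm = NA_real_, n_pred = na, n_gt = nb,
                            status = "vacuous"))
    }
    if (na == 0 || nb == 0) {
      return(tibble::tibble(class_id = k, class_name = name, position = pos,
                            dice = 0, iou = 0, hd_mm = NA_real_,
                            asd_mm = NA_real_, n_pred = na, n_gt = nb,
                            status = if (na == 0) "missing_pred" else
                              "missing_gt"))
    }
    d <- surface_distances(a, b, pred$spacing)
    tibble::tibble(class_id = k, class_name = name, position = pos,
                   dice = 2 * sum(a & b) / (na + nb),
                   iou = sum(a & b) / sum(a | b),
                   hd_mm = max(max(d$pred_to_gt), max(d$gt_to_pred)),
                   asd_mm = mean(c(d$pred_to_gt, d$gt_to_pred)),
                   n_pred = na, n_gt = nb, status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' Aggregate per-case metric reports into summary tables
#'
#' Produces the standard presentation: per-class mean and sample standard
#' deviation across cases, the unweighted "Average" row over classes, and a
#' per-tooth-position (T1-T8) Dice table. Vacuous entries (class absent from
#' both volumes) are excluded. Column order is Dice, mIoU, HD, ASD.
#'
#' @param reports List of `metric_report` tibbles from [evaluate_case()]
#'   (or a single report).
#' @return List of tibbles: `by_class` (with the trailing `Average` row) and
#'   `by_position`.
#' @export
aggregate_reports <- function(reports) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  if (length(reports) == 0)
    cbct_abort("`reports` is empty.", "empty_reports")
  all_rows <- dplyr::bind_rows(
    purrr::imap(reports, function(r, i) dplyr::mutate(r, case = i)))
  usable <- dplyr::filter(all_rows, .data$status != "vacuous")

  agg <- function(df, key) {
    df %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
      dplyr::summarise(
        dice_mean = mean(.data$dice), dice_sd = sd0(.data$dice),
        iou_mean = mean(.data$iou), iou_sd = sd0(.data$iou),
        hd_mean = mean(.data$hd_mm, na.rm = TRUE),
        hd_sd = sd0(.data$hd_mm[!is.na(.data$hd_mm)]),
        asd_mean = mean(.data$asd_mm, na.rm = TRUE),
        asd_sd = sd0(.data$asd_mm[!is.na(.data$asd_mm)]),
        n_cases = dplyr::n(), .groups = "drop")
  }
  by_class <- agg(usable, "class_name")
  avg <- tibble::tibble(
    class_name = "Average",
    dice_mean = mean(by_class$dice_mean), dice_sd = sd0(by_class$dice_mean),
    iou_mean = mean(by_class$iou_mean), iou_sd = sd0(by_class$iou_mean),
    hd_mean = mean(by_class$hd_mean, na.rm = TRUE),
    hd_sd = sd0(by_class$hd_mean[!is.na(by_class$hd_mean)]),
    asd_mean = mean(by_class$asd_mean, na.rm = TRUE),
    asd_sd = sd0(by_class$asd_mean[!is.na(by_class$asd_mean)]),
    n_cases = NA_integer_)
  by_position <- usable %>%
    dplyr::filter(!is.na(.data$position)) %>%
    agg("position") %>%
    dplyr::arrange(.data$position)
  list(by_class = dplyr::bind_rows(by_class, avg),
       by_position = by_position)
}

# sample sd that is 0 (not NA) for a single observation
sd0 <- function(x) {
  if (length(x) < 2) return(0)
  stats::sd(x)
}

#' Plot a metric report as per-class bars
#'
#' @param object A `metric_report` from [evaluate_case()].
#' @param metric One of `"dice"`, `"iou"`, `"hd_mm"`, `"asd_mm"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, metric = "dice", ...) {
  metric <- match.arg(metric, c("dice", "iou", "hd_mm", "asd_mm"))
  df <- dplyr::filter(object, .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_name,
                                   y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
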