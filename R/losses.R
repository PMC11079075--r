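#' Loss configuration for the combined CE + Dice objective
#'
#' @param w_ce Weight of the cross-entropy term (default 1).
#' @param w_dice Weight of the soft Dice term (default 1).
#' @param class_weights Per-class weights `w_j` for the cross-entropy term;
#'   `NULL` means 1 for every class.
#' @param epsilon Smoothing constant: probability floor inside the CE log
#'   and additive denominator guard for Dice terms of classes absent from
#'   both prediction and truth (default 1e-5).
#' @param per_voxel_mean If `TRUE`, the cross-entropy is additionally divided
#'   by the voxel count `N`. The default `FALSE` keeps the printed form of
#'   the objective (1/C only), which scales with patch size.
#' @return A `loss_config` list.
#' @export
loss_config <- function(w_ce = 1, w_dice = 1, class_weights = NULL,
                        epsilon = 1e-5, per_voxel_mean = FALSE) {
  if (w_ce < 0 || w_dice < 0)
    cbct_abort("loss weights must be non-negative.", "bad_config")
  if (!is.null(class_weights) && any(class_weights < 0))
    cbct_abort("class weights must be non-negative.", "bad_config")
  if (epsilon <= 0)
    cbct_abort("`epsilon` must be positive.", "bad_config")
  structure(list(w_ce = w_ce, w_dice = w_dice, class_weights = class_weights,
                 epsilon = epsilon, per_voxel_mean = per_voxel_mean),
            class = "loss_config")
}

#' One-hot encode integer labels
#'
#' @param labels A [cbct_labels()], 3D array, or integer vector.
#' @param class_list Class values defining the column order.
#' @return An `N x C` 0/1 matrix `G` with `colnames(G) == class_list`; every
#'   row sums to exactly 1.
#' @export
one_hot_encode <- function(labels, class_list) {
  v <- if (inherits(labels, "cbct_volume")) as.vector(labels$values) else
    as.vector(labels)
  col <- match(v, class_list)
  if (anyNA(col)) {
    bad <- unique(v[is.na(col)])
    cbct_abort(sprintf("label value(s) not in class_list: %s",
                       paste(bad, collapse = ", ")), "unknown_label")
  }
  G <- matrix(0, nrow = length(v), ncol = length(class_list),
              dimnames = list(NULL, as.character(class_list)))
  G[cbind(seq_along(v), col)] <- 1
  G
}

check_pg <- function(P, G) {
  if (!is.matrix(P) || !is.matrix(G) || !identical(dim(P), dim(G)))
    cbct_abort("P and G must be matrices of identical dimension (N x C).",
               "shape_mismatch")
  invisible(TRUE)
}

#' Class-averaged weighted cross-entropy loss
#'
#' \deqn{L_{CE} = -\frac{1}{C}\sum_{j=1}^{C}\sum_{i=1}^{N}
#'       w_j\, G_{i,j} \log P_{i,j}}
#'
#' where `P` holds predicted per-voxel class probabilities and `G` the
#' one-hot ground truth. Note the printed form carries no `1/N`; set
#' `per_voxel_mean = TRUE` in the config for a patch-size-independent
#' variant. Probabilities are floored at `config$epsilon` inside the log.
#'
#' @param P `N x C` probability matrix (rows sum to 1).
#' @param G `N x C` one-hot matrix, e.g. from [one_hot_encode()].
#' @param config A [loss_config()].
#' @return Scalar loss (>= 0).
#' @export
ce_loss <- function(P, G, config = loss_config()) {
  check_pg(P, G)
  C <- ncol(P)
  w <- config$class_weights %||% rep(1, C)
  if (length(w) != C)
    cbct_abort("class_weights length must equal the number of classes.",
               "shape_mismatch")
  per_class <- colSums(G * log(pmax(P, config$epsilon)))
  loss <- -sum(w * per_class) / C
  if (config$per_voxel_mean) loss <- loss / nrow(P)
  loss
}

#' Multi-class soft Dice loss
#'
#' \deqn{L_{Dice} = 1 - \frac{2}{C}\sum_{j=1}^{C}
#'   \frac{\sum_i P_{i,j} G_{i,j}}
#'        {\sum_i P_{i,j}^2 + \sum_i G_{i,j}^2 + \epsilon}}
#'
#' The additive `epsilon` in the denominator resolves classes absent from
#' both prediction and truth (their term contributes 0).
#'
#' @inheritParams ce_loss
#' @return Scalar loss in `[0, 1]` (up to epsilon slack).
#' @export
dice_loss <- function(P, G, config = loss_config()) {
  check_pg(P, G)
  C <- ncol(P)
  num <- colSums(P * G)
  den <- colSums(P^2) + colSums(G^2) + config$epsilon
  1 - (2 / C) * sum(num / den)
}

#' Combined training objective
#'
#' `Loss = w_CE * Loss_CE + w_Dice * Loss_Dice` with both weights defaulting
#' to 1.
#'
#' @inheritParams ce_loss
#' @return Scalar loss.
#' @examples
#' G <- one_hot_encode(c(0, 1, 1, 0), class_list = c(0, 1))
#' combined_loss(G, G)  # perfect prediction -> ~0
#' @export
combined_loss <- function(P, G, config = loss_config()) {
  config$w_ce * ce_loss(P, G, config) +
    config$w_dice * dice_loss(P, G, config)
}
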