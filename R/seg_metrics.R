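#' Overlap metrics and the combined Dice + BCE training loss
#'
#' The Dice coefficient between a reference mask and a (possibly soft)
#' prediction is
#' \deqn{\mathrm{Dice} = \frac{2\sum y_{true} \, y_{pred} + smooth}
#'   {\sum y_{true} + \sum y_{pred} + smooth}}
#' with `smooth` a small constant preventing division by zero. For hard
#' masks the Jaccard index (intersection over union) obeys
#' `jaccard = dice / (2 - dice)`.
#'
#' @param y_true Reference mask ([mask3d], logical or numeric array in
#'   `[0, 1]`).
#' @param y_pred Predicted array in `[0, 1]`, same shape.
#' @param smooth Stabilizing constant (default `1e-5`).
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(y_true, y_pred, smooth = 1e-5) {
  y_true <- as_unit_array(y_true)
  y_pred <- as_unit_array(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch", call. = FALSE)
  (2 * sum(y_true * y_pred) + smooth) / (sum(y_true) + sum(y_pred) + smooth)
}

#' @rdname dice_coefficient
#' @export
jaccard_index <- function(y_true, y_pred, smooth = 1e-5) {
  y_true <- as_unit_array(y_true)
  y_pred <- as_unit_array(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch", call. = FALSE)
  inter <- sum(y_true * y_pred)
  (inter + smooth) / (sum(y_true) + sum(y_pred) - inter + smooth)
}

#' @rdname dice_coefficient
#' @param eps Clipping bound applied to `y_pred` before the logarithms
#'   (default `1e-7`).
#' @return `combined_loss`: `0.5 * (1 - Dice) + 0.5 * BCE` where BCE is the
#'   per-voxel mean binary cross-entropy.
#' @export
combined_loss <- function(y_true, y_pred, smooth = 1e-5, eps = 1e-7) {
  y_true <- as_unit_array(y_true)
  y_pred <- as_unit_array(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch", call. = FALSE)
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  bce <- -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  0.5 * (1 - dice_coefficient(y_true, y_pred, smooth)) + 0.5 * bce
}

as_unit_array <- function(x) {
  if (inherits(x, "mask3d")) x <- x$data
  x <- x * 1.0
  if (is.null(dim(x))) dim(x) <- length(x)
  x
}
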