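#' Numerically stable softmax
#'
#' `exp(x_i) / sum_j exp(x_j)` with the maximum subtracted first, so the
#' result is shift-invariant and never overflows.
#'
#' @param logits numeric vector of finite scores.
#' @return Probability vector of the same length (positive, sums to 1).
#' @export
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop("logits must be finite")
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Soft-IoU (Jaccard) segmentation loss
#'
#' `1 - sum(p * g) / (sum(p) + sum(g) - sum(p * g))`, where `p` are
#' foreground softmax probabilities and `g` is the binary gold-standard
#' mask. The soft (probabilistic) intersection makes the loss differentiable
#' in `p`; on binary `p` it equals one minus the Jaccard index exactly. The
#' value lies in [0, 1] and is 0 only for perfect overlap.
#'
#' The degenerate empty-vs-empty case (`sum(p) + sum(g) = 0`) is defined as
#' loss 0 with a warning: an empty prediction of an empty mask is perfect.
#'
#' @param p numeric array of foreground probabilities in [0, 1].
#' @param g binary array of the same shape.
#' @return Scalar loss in [0, 1].
#' @seealso [iou_loss_grad()] for the analytic gradient, [iou_metric()] for
#'   the evaluation-side complement.
#' @export
iou_loss <- function(p, g) {
  p <- as_vol_array(p); g <- as_vol_array(g)
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop("`p` and `g` must have the same shape")
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("`g` must be binary")
  inter <- sum(p * g)
  uni <- sum(p) + sum(g) - inter
  if (uni == 0) {
    warning("empty prediction vs empty mask: IoU loss defined as 0")
    return(0)
  }
  1 - inter / uni
}

#' Analytic gradient of the soft-IoU loss
#'
#' d/dp_i of [iou_loss()]: with I = sum(p g) and U = sum(p) + sum(g) - I,
#' the derivative is `-(g_i * U - I * (1 - g_i)) / U^2`.
#'
#' @param p foreground probabilities.
#' @param g binary mask of the same shape.
#' @return Array of the same shape as `p` (zero if the union is empty).
#' @export
iou_loss_grad <- function(p, g) {
  p <- as_vol_array(p); g <- as_vol_array(g)
  inter <- sum(p * g)
  uni <- sum(p) + sum(g) - inter
  if (uni == 0) return(array(0, dim(p) %||% length(p)))
  -(g * uni - inter * (1 - g)) / uni^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-entropy loss for state classification
#'
#' `-sum(t * log(y))` over classes, with `t` one-hot and `y` a probability
#' vector. Used for the slice-level pathological-state (amyloid
#' positive/negative) head. Probabilities of zero at the true class are
#' clamped at `eps` to keep the loss finite.
#'
#' @param t one-hot truth vector.
#' @param y probability vector (non-negative, sums to 1 within 1e-6).
#' @param eps clamp for `log(0)`; default 1e-12.
#' @return Non-negative scalar; 0 iff `y` puts all mass on the true class.
#' @export
cross_entropy <- function(t, y, eps = 1e-12) {
  if (length(t) != length(y)) stop("`t` and `y` must have equal length")
  if (!isTRUE(all.equal(sum(t), 1)) || !all(t %in% c(0, 1)))
    stop("`t` must be one-hot")
  if (any(y < 0) || abs(sum(y) - 1) > 1e-6)
    stop("`y` must be a probability vector")
  -sum(t * log(pmax(y, eps)))
}

#' Mean pixelwise cross-entropy between a probability map and a mask
#'
#' The two-class cross-entropy of Eq.-style one-hot targets derived from a
#' binary mask, averaged over pixels. Exposed as the optional auxiliary term
#' of the training objective (`iou + lambda * ce`).
#'
#' @param p_fg foreground-probability array.
#' @param g binary mask of the same shape.
#' @param eps clamp for `log(0)`.
#' @return Non-negative scalar.
#' @export
pixel_cross_entropy <- function(p_fg, g, eps = 1e-12) {
  p_fg <- as_vol_array(p_fg); g <- as_vol_array(g)
  if (!identical(dim(p_fg), dim(g))) stop("shape mismatch")
  -mean(g * log(pmax(p_fg, eps)) + (1 - g) * log(pmax(1 - p_fg, eps)))
}
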