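#' Binarize a probability map
#'
#' A pixel is foreground iff its foreground probability strictly exceeds
#' `threshold`, so an exactly 0.5/0.5 pixel stays background.
#'
#' @param p `[H, W, 2]` probability array (foreground = channel 2), or a 2D
#'   matrix of foreground probabilities.
#' @param threshold decision threshold; default 0.5.
#' @return Binary matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  p_fg <- if (length(dim(p)) == 3L) p[, , 2] else p
  (p_fg > threshold) * 1
}

#' Morphological dilation of a binary mask
#'
#' 2D masks are dilated with a `size x size` square structuring element via
#' EBImage; 3D masks with a `size^3` cube (full square/cubic connectivity).
#' Dilation only ever grows a mask.
#'
#' @param mask binary 2D matrix or 3D array.
#' @param size odd structuring-element edge length; default 3.
#' @return Dilated binary mask of the same shape.
#' @export
dilate_mask <- function(mask, size = 3L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("`size` must be a positive odd")
  a <- as_vol_array(mask)
  if (!all(a %in% c(0, 1))) stop("mask must be binary")
  if (size == 1L) return(a)
  r <- (size - 1L) %/% 2L
  if (length(dim(a)) == 2L) {
    kern <- matrix(1, size, size)
    out <- EBImage::dilate(a, kern)
    return((matrix(as.numeric(EBImage::imageData(out)),
                   nrow(a)) > 0.5) * 1)
  }
  # 3D: union of all shifts within the cube
  d <- dim(a)
  out <- array(0, d)
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- pmax(out[xs, ys, zs],
                            a[xs - dx, ys - dy, zs - dz])
  }
  out
}

#' Hemispheric-swap fixed thresholding
#'
#' Refines a predicted lesion mask using the subject's own contralateral
#' side as the reference: the slice is mirrored left-right, the mean
#' intensity under the mirrored predicted mask gives the reference level,
#' and only predicted pixels whose intensity strictly exceeds
#' `factor x reference` survive. On a perfectly symmetric slice (lesion
#' intensity equal to its mirror) any factor above 1 therefore empties the
#' mask. The output is always a subset of the input mask.
#'
#' @param slice 2D intensity image (pons-normalized); dimension
#'   `mirror_axis` is the left-right axis.
#' @param pred_mask binary predicted mask of the same shape.
#' @param factor threshold multiplier; the study protocol uses 1.3 (note:
#'   deliberately distinct from the 1.5 ground-truth factor).
#' @param mirror_axis 1 (rows, the x/left-right convention here) or 2.
#' @return Binary mask, subset of `pred_mask`. If the mirrored mask is
#'   empty the input is returned unchanged with a warning.
#' @export
hemispheric_swap_threshold <- function(slice, pred_mask, factor = 1.3,
                                       mirror_axis = 1L) {
  if (!identical(dim(slice), dim(pred_mask)))
    stop("slice and mask must have the same shape")
  if (!all(pred_mask %in% c(0, 1))) stop("`pred_mask` must be binary")
  if (factor < 0) stop("`factor` must be non-negative")
  mirrored <- if (mirror_axis == 1L) pred_mask[nrow(pred_mask):1, ]
              else pred_mask[, ncol(pred_mask):1]
  if (sum(mirrored) == 0) {
    warning("mirrored mask is empty; returning prediction unchanged")
    return(pred_mask)
  }
  ref <- mean(slice[mirrored == 1])
  ((pred_mask == 1) & (slice > factor * ref)) * 1
}

#' Full post-processing of one predicted slice
#'
#' binarize -> morphological dilation -> hemispheric-swap threshold, the
#' order used to turn raw softmax maps into final lesion masks.
#'
#' @param slice the (pons-normalized) intensity slice.
#' @param probs `[H, W, 2]` probability map (or foreground matrix).
#' @param factor hemispheric-swap threshold multiplier; default 1.3.
#' @param dilate structuring-element size for dilation; 0 or 1 skips it.
#' @param mirror_axis left-right axis of the slice.
#' @return Binary lesion mask.
#' @export
postprocess_prediction <- function(slice, probs, factor = 1.3, dilate = 3L,
                                   mirror_axis = 1L) {
  m <- binarize(probs)
  if (dilate >= 2L) m <- dilate_mask(m, dilate)
  if (sum(m) == 0) return(m)
  hemispheric_swap_threshold(slice, m, factor = factor,
                             mirror_axis = mirror_axis)
}
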