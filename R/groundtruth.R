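#' Thresholding rule for ground-truth masks
#'
#' Ground-truth lesion masks are produced semi-automatically: a manually
#' delineated zone is intersected with the voxels exceeding `factor` times a
#' background intensity level. The clinical convention is a factor of 1.5
#' over a cerebellar-gray/pons-normalized background.
#'
#' @param factor positive multiplier on the background level (default 1.5).
#' @param background the background intensity level, usually from
#'   [background_level()]; must be > 0 when the rule is applied.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(factor = 1.5, background = NULL) {
  if (!is.numeric(factor) || factor <= 0) stop("`factor` must be positive")
  structure(list(factor = factor, background = background),
            class = "threshold_rule")
}

#' Mean intensity of a background reference region
#'
#' @param vol a [pet_volume()].
#' @param background_mask non-empty [zone_mask()] over the background region.
#' @return The arithmetic mean of the voxels under the mask.
#' @export
background_level <- function(vol, background_mask) {
  a <- as_vol_array(vol)
  m <- as_vol_array(background_mask)
  if (!identical(dim(a), dim(m)))
    stop("background mask shape does not match the volume")
  if (sum(m) == 0) stop("background mask is empty")
  mean(a[m == 1])
}

#' Derive a ground-truth lesion mask by zone-restricted thresholding
#'
#' Emulates the manual-delineation-plus-threshold procedure: within the zone
#' mask, voxels whose (normalized) intensity strictly exceeds
#' `factor x background` are labelled lesion. The output is always a subset
#' of the zone. Strict inequality is used at the threshold, so voxels exactly
#' at `factor x background` are excluded.
#'
#' @param vol a normalized [pet_volume()].
#' @param zone a non-empty [zone_mask()] delineating the search region.
#' @param rule a [threshold_rule()] carrying `factor` and `background`.
#' @return A [zone_mask()] with the same `zone_id` as `zone`.
#' @export
make_ground_truth <- function(vol, zone, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  a <- as_vol_array(vol)
  z <- as_vol_array(zone)
  if (!identical(dim(a), dim(z)))
    stop("zone mask shape does not match the volume")
  if (sum(z) == 0) stop("zone mask is empty")
  bg <- rule$background
  if (is.null(bg) || !is.finite(bg) || bg <= 0)
    stop("rule background level must be a positive number")
  out <- (z == 1) & (a > rule$factor * bg)
  zone_mask(zone$zone_id, out * 1)
}
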