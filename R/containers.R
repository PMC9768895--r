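#' Canonical amyloid zone identifiers
#'
#' The five cortical/subcortical zones rated in clinical amyloid PET reads:
#' frontal lobe, posterior cingulate cortex + precuneus, lateral temporal
#' lobe, inferolateral parietal lobe, and striatum.
#'
#' @export
ZONE_IDS <- c("frontal", "pcc_precuneus", "lateral_temporal", "parietal",
              "striatum")

#' Construct a PET volume
#'
#' A `pet_volume` carries a 3D non-negative intensity array together with its
#' voxel spacing in millimetres. Axis convention: dimension 1 is x
#' (left-right, the mirror axis for hemispheric swaps), dimension 2 is y
#' (anterior-posterior), dimension 3 is z (inferior-superior). Axial slices
#' fix z, coronal slices fix y, sagittal slices fix x.
#'
#' @param data 3D numeric array, all values finite and non-negative.
#' @param voxel_size_mm voxel edge length(s) in mm; scalar or length-3.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(data, voxel_size_mm = 2.0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("`data` must be finite everywhere")
  if (any(data < 0))
    stop("`data` must be non-negative")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be a positive scalar or length-3 vector")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' Construct a binary zone mask
#'
#' A `zone_mask` is a binary 3D array labelled with the zone it delineates.
#' It is the container for gold-standard masks (the per-voxel g values of the
#' Jaccard loss) as well as for reference regions (pons, background).
#'
#' @param zone_id character label; one of [ZONE_IDS] or a reference-region
#'   label such as `"pons"` or `"background"`.
#' @param data 3D array with values in \{0, 1\} (logical accepted).
#' @return An object of class `zone_mask`.
#' @export
zone_mask <- function(zone_id, data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  structure(list(zone_id = as.character(zone_id), data = data),
            class = "zone_mask")
}

#' @export
print.zone_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zone_mask> '%s': %d x %d x %d, %d voxels set\n",
              x$zone_id, d[1], d[2], d[3], as.integer(sum(x$data))))
  invisible(x)
}

#' @export
dim.zone_mask <- function(x) dim(x$data)

# Coerce pet_volume/zone_mask/array uniformly to a bare array.
as_vol_array <- function(x) {
  if (inherits(x, "pet_volume") || inherits(x, "zone_mask")) x$data else x
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
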