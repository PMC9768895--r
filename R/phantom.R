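#' Define a phantom amyloid zone
#'
#' A zone is a union of simple parametric solids (ellipsoids and axis-aligned
#' boxes) in 0-based voxel coordinates, labelled positive or negative for
#' amyloid uptake. Positive zones receive `uptake_ratio` times the background
#' tracer concentration; negative zones blend into background (ratio 1).
#'
#' @param zone_id one of [ZONE_IDS], or a reference-region label.
#' @param geometry list of solids; each solid is a list with `type`
#'   (`"ellipsoid"` or `"box"`) plus `center`/`semiaxes` (ellipsoid, voxel
#'   units) or `lower`/`upper` (box, inclusive voxel bounds).
#' @param positive logical; does the zone accumulate tracer?
#' @param uptake_ratio uptake relative to background; must be 1 exactly when
#'   `positive` is `FALSE` and >= 1 when `TRUE`.
#' @return An object of class `zone_def`.
#' @export
zone_def <- function(zone_id, geometry, positive = TRUE,
                     uptake_ratio = if (positive) 2.0 else 1.0) {
  if (!is.list(geometry) || length(geometry) == 0L)
    stop("`geometry` must be a non-empty list of solids")
  for (g in geometry) {
    if (!is.list(g) || is.null(g$type))
      stop("each solid needs a `type`")
    if (!g$type %in% c("ellipsoid", "box"))
      stop("solid type must be 'ellipsoid' or 'box'")
    if (g$type == "ellipsoid" &&
        (length(g$center) != 3L || length(g$semiaxes) != 3L ||
         any(g$semiaxes <= 0)))
      stop("ellipsoid needs 3-vector `center` and positive `semiaxes`")
    if (g$type == "box" &&
        (length(g$lower) != 3L || length(g$upper) != 3L ||
         any(g$upper < g$lower)))
      stop("box needs `lower` <= `upper`, both 3-vectors")
  }
  positive <- isTRUE(positive)
  if (!positive && uptake_ratio != 1)
    stop("negative zones must have uptake_ratio = 1")
  if (positive && uptake_ratio < 1)
    stop("positive zones must have uptake_ratio >= 1")
  structure(list(zone_id = as.character(zone_id), geometry = geometry,
                 positive = positive, uptake_ratio = uptake_ratio),
            class = "zone_def")
}

ellipsoid <- function(center, semiaxes)
  list(type = "ellipsoid", center = center, semiaxes = semiaxes)

box_solid <- function(lower, upper)
  list(type = "box", lower = lower, upper = upper)

# Rasterize a union of solids into a binary array (0-based voxel coords).
rasterize_geometry <- function(geometry, matrix_size) {
  nx <- matrix_size[1]; ny <- matrix_size[2]; nz <- matrix_size[3]
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1; zs <- seq_len(nz) - 1
  out <- array(FALSE, matrix_size)
  for (g in geometry) {
    if (g$type == "ellipsoid") {
      dx2 <- ((xs - g$center[1]) / g$semiaxes[1])^2
      dy2 <- ((ys - g$center[2]) / g$semiaxes[2])^2
      dz2 <- ((zs - g$center[3]) / g$semiaxes[3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    } else {
      inx <- xs >= g$lower[1] & xs <= g$upper[1]
      iny <- ys >= g$lower[2] & ys <= g$upper[2]
      inz <- zs >= g$lower[3] & zs <= g$upper[3]
      inside <- outer(outer(inx, iny, "&"), inz, "&")
    }
    out <- out | inside
  }
  storage.mode(out) <- "double"
  out
}

#' Specify a synthetic amyloid-PET phantom
#'
#' Bundles everything [generate_phantom()] needs: matrix size, voxel spacing,
#' the amyloid zone definitions, the pons reference region, an optional
#' background reference region (a cerebellar-gray surrogate used by the
#' thresholding ground-truth rule), background uptake, the point-spread
#' blur (FWHM of an isotropic Gaussian, in mm), additive Gaussian noise, and
#' the RNG seed.
#'
#' @param matrix_size integer triple (voxels); default `c(64, 64, 40)`, a
#'   desk-scale stand-in for clinical 256 x 256 matrices.
#' @param voxel_size_mm voxel edge length in mm (clinical default 2.0).
#' @param zones list of [zone_def()] objects; pairwise disjoint.
#' @param pons list with `center` and `radius` (voxel units); the midline
#'   reference region whose mean is scaled to 1 by normalization.
#' @param background_region optional solid (see [zone_def()] geometry) whose
#'   mean intensity defines "background" for thresholding; defaults to a
#'   small midline inferior-posterior ellipsoid (cerebellar surrogate).
#' @param background_uptake tracer concentration outside zones; must be > 0.
#' @param brain optional list with `center`, `semiaxes`, `air_value`: voxels
#'   outside this ellipsoid get `air_value` instead of background, giving the
#'   volume a brain-shaped envelope. `NULL` (default) fills uniformly.
#' @param noise_sigma standard deviation of additive Gaussian noise (applied
#'   after blurring; negative results are clamped to 0).
#' @param psf_fwhm_mm full width at half maximum of the Gaussian point-spread
#'   blur, mm (clinical reconstruction uses 3.0 mm).
#' @param seed integer RNG seed; fixes the noise realization.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(64L, 64L, 40L),
                         voxel_size_mm = 2.0,
                         zones = list(),
                         pons = list(center = c(31.5, 40, 8), radius = 3.5),
                         background_region = NULL,
                         background_uptake = 1.0,
                         brain = NULL,
                         noise_sigma = 0,
                         psf_fwhm_mm = 0,
                         seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3L || any(matrix_size < 4L))
    stop("`matrix_size` must be a triple of integers >= 4")
  if (background_uptake <= 0)
    stop("`background_uptake` must be positive")
  if (noise_sigma < 0 || psf_fwhm_mm < 0)
    stop("`noise_sigma` and `psf_fwhm_mm` must be non-negative")
  for (z in zones)
    if (!inherits(z, "zone_def")) stop("`zones` must be zone_def objects")
  if (is.null(background_region))
    background_region <- ellipsoid(
      center = c((matrix_size[1] - 1) / 2,
                 matrix_size[2] * 0.78, matrix_size[3] * 0.15),
      semiaxes = pmax(matrix_size * c(0.10, 0.08, 0.08), 1.5))
  structure(list(matrix_size = matrix_size,
                 voxel_size_mm = voxel_size_mm,
                 zones = zones, pons = pons,
                 background_region = background_region,
                 background_uptake = background_uptake,
                 brain = brain,
                 noise_sigma = noise_sigma,
                 psf_fwhm_mm = psf_fwhm_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default five-zone brain phantom
#'
#' A desk-scale phantom with all five amyloid zones laid out with the right
#' topology: four bilateral zone pairs mirrored about the mid-sagittal plane
#' (so hemispheric swaps have a contralateral homologue), a midline posterior
#' PCC/precuneus zone, a midline pons, and a cerebellar background reference
#' region. Geometry is parametric, not anatomical.
#'
#' @param matrix_size integer triple; default `c(64, 64, 40)`.
#' @param positive named logical vector over [ZONE_IDS]; which zones show
#'   amyloid accumulation. Default: all positive.
#' @param uptake_ratio uptake of positive zones relative to background.
#' @param jitter non-negative scalar; if > 0, zone centers and semiaxes are
#'   perturbed by up to `jitter` voxels (uniform, seeded) to vary anatomy
#'   across subjects. Bilateral symmetry is preserved.
#' @param brain_envelope logical; add a brain-shaped envelope (air outside).
#' @param ... passed on to [phantom_spec()] (`noise_sigma`, `psf_fwhm_mm`,
#'   `background_uptake`, `seed`, ...).
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(matrix_size = c(64L, 64L, 40L),
                                 positive = stats::setNames(
                                   rep(TRUE, 5), ZONE_IDS),
                                 uptake_ratio = 2.0,
                                 jitter = 0,
                                 brain_envelope = FALSE,
                                 ...) {
  matrix_size <- as.integer(matrix_size)
  s <- matrix_size / c(64, 64, 40)          # scale from the reference layout
  mid <- (matrix_size[1] - 1) / 2           # mirror plane x = mid
  dots <- list(...)
  seed <- if (!is.null(dots$seed)) dots$seed else 1L

  jit <- function(k, n) {
    if (jitter <= 0) rep(0, n)
    else with_seed(seed * 1000L + k, stats::runif(n, -jitter, jitter))
  }
  # Bilateral pair of ellipsoids mirrored about x = mid.
  bilateral <- function(center, semiaxes, k) {
    j <- jit(k, 6)
    ce <- center + j[1:3]; se <- pmax(semiaxes + j[4:6] * 0.5, 1.5)
    list(ellipsoid(ce, se),
         ellipsoid(c(2 * mid - ce[1], ce[2], ce[3]), se))
  }
  midline <- function(center, semiaxes, k) {
    j <- jit(k, 5)
    list(ellipsoid(c(mid, center[2] + j[1], center[3] + j[2]),
                   pmax(semiaxes + j[3:5] * 0.5, 1.5)))
  }

  geom <- list(
    frontal          = bilateral(c(19, 13, 24) * s, c(6.5, 5.5, 5.5) * s, 1L),
    pcc_precuneus    = midline(c(NA, 49, 24) * c(1, s[2], s[3]),
                               c(5.5, 4.5, 4.5) * s, 2L),
    lateral_temporal = bilateral(c(9, 31, 13) * s, c(3.5, 6.5, 4.5) * s, 3L),
    parietal         = bilateral(c(19, 45, 30) * s, c(5.5, 4.5, 4.0) * s, 4L),
    striatum         = bilateral(c(23, 27, 20) * s, c(3.5, 5.0, 3.5) * s, 5L)
  )
  positive <- positive[ZONE_IDS]
  zones <- lapply(ZONE_IDS, function(id)
    zone_def(id, geom[[id]], positive = positive[[id]],
             uptake_ratio = if (isTRUE(positive[[id]])) uptake_ratio else 1.0))

  brain <- if (brain_envelope)
    list(center = c(mid, (matrix_size[2] - 1) / 2, (matrix_size[3] - 1) / 2),
         semiaxes = matrix_size * c(0.47, 0.48, 0.46), air_value = 0)
  else NULL

  phantom_spec(matrix_size = matrix_size,
               zones = zones,
               pons = list(center = c(mid, 40 * s[2], 7 * s[3]),
                           radius = max(3.5 * min(s), 1.5)),
               brain = brain, ...)
}

# Separable Gaussian blur along all three axes; kernel rows renormalized at
# the edges so constant volumes stay constant.
gaussian_blur3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  blur_axis <- function(a, axis) {
    n <- dim(a)[axis]
    x <- seq_len(n)
    K <- exp(-(outer(x, x, "-"))^2 / (2 * sigma_vox^2))
    K[K < 1e-12] <- 0
    K <- K / rowSums(K)
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- K %*% m
    out <- array(out, dim(ap))
    aperm(out, order(perm))
  }
  for (ax in 1:3) arr <- blur_axis(arr, ax)
  arr
}

#' Generate a synthetic amyloid-PET volume with gold-standard masks
#'
#' Rasterizes the zones of a [phantom_spec()] into an intensity volume:
#' background uptake everywhere (or inside the brain envelope when one is
#' specified), positive zones at `uptake_ratio` times background, then an
#' isotropic Gaussian point-spread blur of the stated FWHM and additive
#' Gaussian noise (clamped at zero). Fully deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [pet_volume()]), `zones` (list of
#'   [zone_mask()], one per zone in `spec`), `pons` (a `zone_mask`),
#'   `background` (a `zone_mask` over the background reference region), and
#'   `spec` (the input, echoed for provenance).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ms <- spec$matrix_size
  masks <- lapply(spec$zones, function(z)
    zone_mask(z$zone_id, rasterize_geometry(z$geometry, ms)))
  pons_m <- zone_mask("pons", rasterize_geometry(
    list(ellipsoid(spec$pons$center, rep(spec$pons$radius, 3))), ms))
  bg_m <- zone_mask("background", rasterize_geometry(
    list(spec$background_region), ms))
  if (sum(pons_m$data) == 0) stop("pons region rasterizes to zero voxels")

  overlap <- Reduce(`+`, lapply(masks, `[[`, "data")) + pons_m$data
  if (max(overlap) > 1)
    stop("zone regions (and pons) must be pairwise disjoint")

  vol <- array(spec$background_uptake, ms)
  if (!is.null(spec$brain)) {
    inside <- rasterize_geometry(
      list(ellipsoid(spec$brain$center, spec$brain$semiaxes)), ms)
    vol[inside == 0] <- spec$brain$air_value
  }
  for (i in seq_along(spec$zones)) {
    z <- spec$zones[[i]]
    if (z$positive)
      vol[masks[[i]]$data == 1] <- z$uptake_ratio * spec$background_uptake
  }

  if (spec$psf_fwhm_mm > 0) {
    vs <- if (length(spec$voxel_size_mm) == 1L) spec$voxel_size_mm
          else mean(spec$voxel_size_mm)
    sigma_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / vs
    vol <- gaussian_blur3d(vol, sigma_vox)
  }
  if (spec$noise_sigma > 0) {
    vol <- with_seed(spec$seed,
                     vol + array(stats::rnorm(prod(ms), 0, spec$noise_sigma),
                                 ms))
    vol[vol < 0] <- 0
  }

  list(volume = pet_volume(vol, spec$voxel_size_mm),
       zones = stats::setNames(masks, vapply(spec$zones, `[[`, "",
                                             "zone_id")),
       pons = pons_m, background = bg_m, spec = spec)
}

#' Extract 2D slices from a volume
#'
#' @param vol a [pet_volume()], [zone_mask()], or 3D array.
#' @param plane `"axial"` (fixed z), `"coronal"` (fixed y), or `"sagittal"`
#'   (fixed x).
#' @param indices 1-based slice indices along the fixed axis.
#' @return A list of 2D matrices, one per index, named by index.
#' @export
extract_slices <- function(vol, plane = c("axial", "coronal", "sagittal"),
                           indices) {
  plane <- match.arg(plane)
  a <- as_vol_array(vol)
  d <- dim(a)
  axis <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > d[axis]))
    stop(sprintf("slice index out of bounds for %s plane (1..%d)",
                 plane, d[axis]))
  out <- lapply(indices, function(i)
    switch(plane,
           axial    = a[, , i],
           coronal  = a[, i, ],
           sagittal = a[i, , ]))
  stats::setNames(out, indices)
}

#' Re-stack 2D slices into a volume array
#'
#' Inverse of [extract_slices()] when given every index of a plane in order.
#'
#' @param slices list of equally sized 2D matrices.
#' @param plane the plane the slices were taken from.
#' @return A 3D array.
#' @export
stack_slices <- function(slices, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  stopifnot(length(slices) > 0L)
  ds <- dim(slices[[1]])
  n <- length(slices)
  d <- switch(plane,
              axial    = c(ds[1], ds[2], n),
              coronal  = c(ds[1], n, ds[2]),
              sagittal = c(n, ds[1], ds[2]))
  out <- array(0, d)
  for (i in seq_len(n)) {
    s <- slices[[i]]
    switch(plane,
           axial    = {out[, , i] <- s},
           coronal  = {out[, i, ] <- s},
           sagittal = {out[i, , ] <- s})
  }
  out
}

#' Slice indices intersecting a mask
#'
#' Convenience for choosing which slices of a plane contain any voxels of a
#' zone (used to build per-zone 2D training sets).
#'
#' @param mask a [zone_mask()] or 3D array.
#' @param plane slicing plane.
#' @param min_voxels keep slices with at least this many mask voxels.
#' @return Integer vector of slice indices.
#' @export
slices_with_mask <- function(mask, plane = c("axial", "coronal", "sagittal"),
                             min_voxels = 1L) {
  plane <- match.arg(plane)
  a <- as_vol_array(mask)
  axis <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  counts <- apply(a, axis, sum)
  which(counts >= min_voxels)
}
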