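#' Normalize a PET volume to its pons reference
#'
#' Divides every voxel by the arithmetic mean intensity inside the pons mask,
#' so the pons reference region has a ratio of exactly 1 afterwards. This is
#' the standard SUVR-style reference-region normalization that makes amyloid
#' scans comparable across subjects and color scales.
#'
#' @param vol a [pet_volume()].
#' @param pons_mask a [zone_mask()] over the pons; must be non-empty with a
#'   strictly positive mean intensity.
#' @return A list with `volume` (the normalized [pet_volume()]) and `report`,
#'   a `normalization_report` with fields `pons_mean`, `scale_applied`
#'   (`= 1 / pons_mean`) and `method = "pons-ratio"`.
#' @export
normalize_to_pons <- function(vol, pons_mask) {
  stopifnot(inherits(vol, "pet_volume"))
  m <- as_vol_array(pons_mask)
  if (!identical(dim(m), dim(vol$data)))
    stop("pons mask shape does not match the volume")
  if (sum(m) == 0) stop("pons mask is empty")
  pons_mean <- mean(vol$data[m == 1])
  if (!is.finite(pons_mean) || pons_mean <= 0)
    stop("pons mean must be positive")
  out <- pet_volume(vol$data / pons_mean, vol$voxel_size_mm)
  report <- structure(list(pons_mean = pons_mean,
                           scale_applied = 1 / pons_mean,
                           method = "pons-ratio"),
                      class = "normalization_report")
  list(volume = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("<normalization_report> method=%s pons_mean=%.6g scale=%.6g\n",
              x$method, x$pons_mean, x$scale_applied))
  invisible(x)
}

# Linear interpolation weight matrix mapping n samples to m samples
# (align-corners grid: endpoints map to endpoints).
interp_matrix <- function(n, m) {
  if (m < 2L) stop("target dimension must be >= 2")
  if (n == 1L) return(matrix(1, m, 1))
  s <- 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(s), n - 1)
  f <- s - lo
  W <- matrix(0, m, n)
  W[cbind(seq_len(m), lo)] <- 1 - f
  W[cbind(seq_len(m), lo + 1)] <- W[cbind(seq_len(m), lo + 1)] + f
  W
}

#' Resize a volume by separable linear interpolation
#'
#' Axis-separable linear interpolation onto a new grid whose endpoints
#' coincide with the source endpoints. Constant volumes stay constant and
#' output values never leave the input range. Voxel spacing is rescaled per
#' axis to preserve physical extent.
#'
#' @param vol a [pet_volume()] or 3D array.
#' @param target_shape integer triple, each >= 2.
#' @return A resized [pet_volume()] (or bare array if the input was one).
#' @export
resize_volume <- function(vol, target_shape) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stop("`target_shape` must be a triple of integers >= 2")
  a <- as_vol_array(vol)
  d0 <- dim(a)
  for (ax in 1:3) {
    n <- dim(a)[ax]; m <- target_shape[ax]
    if (n == m) next
    W <- interp_matrix(n, m)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    out <- W %*% matrix(ap, nrow = n)
    dims <- dim(ap); dims[1] <- m
    a <- aperm(array(out, dims), order(perm))
  }
  if (inherits(vol, "pet_volume")) {
    vs <- vol$voxel_size_mm * (d0 - 1) / pmax(target_shape - 1, 1)
    pet_volume(a, vs)
  } else a
}

#' Standardize intensities to a mean and standard deviation
#'
#' Applies `(x - mean) / std` voxelwise; the usual zero-mean/unit-variance
#' scaling before feeding images to the network. `mean` and `std` are
#' typically global statistics over the whole dataset (see
#' [dataset_statistics()]).
#'
#' @param vol a [pet_volume()], [zone_mask()] or array; 2D or 3D.
#' @param mean,std the statistics; `std` must be > 0.
#' @return An array (standardized values can be negative, so the result is
#'   returned as a bare array rather than a `pet_volume`).
#' @export
standardize <- function(vol, mean, std) {
  if (!is.finite(std) || std <= 0) stop("`std` must be positive")
  (as_vol_array(vol) - mean) / std
}

#' Global mean and standard deviation of a set of images
#'
#' @param xs list of arrays/matrices (or a single array).
#' @return list with `mean` and `std` pooled over all voxels of all images.
#' @export
dataset_statistics <- function(xs) {
  if (!is.list(xs)) xs <- list(xs)
  v <- unlist(lapply(xs, function(x) as.numeric(as_vol_array(x))))
  list(mean = mean(v), std = stats::sd(v))
}

#' Augmentation parameters
#'
#' One sampled geometric transform: rotation in [-10, 10] degrees,
#' translations in [-0.1, 0.1] of the image width/height, and shear in
#' [-10, 10] degrees. These closed ranges are enforced.
#'
#' @param rotation_deg rotation angle, degrees (counter-clockwise in array
#'   coordinates).
#' @param translate_frac_x,translate_frac_y translation as a fraction of the
#'   image extent along x (dim 1) and y (dim 2).
#' @param shear_deg shear angle along x, degrees.
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(rotation_deg = 0, translate_frac_x = 0,
                                translate_frac_y = 0, shear_deg = 0) {
  if (abs(rotation_deg) > 10) stop("rotation must be within [-10, 10] deg")
  if (abs(translate_frac_x) > 0.1 || abs(translate_frac_y) > 0.1)
    stop("translations must be within [-0.1, 0.1]")
  if (abs(shear_deg) > 10) stop("shear must be within [-10, 10] deg")
  structure(list(rotation_deg = rotation_deg,
                 translate_frac_x = translate_frac_x,
                 translate_frac_y = translate_frac_y,
                 shear_deg = shear_deg),
            class = "augmentation_params")
}

#' Sample random augmentation parameters
#'
#' Uniform draws over the full allowed ranges.
#'
#' @param seed optional seed for a reproducible draw.
#' @return An [augmentation_params()].
#' @export
sample_augmentation <- function(seed = NULL) {
  draw <- function() augmentation_params(
    rotation_deg = stats::runif(1, -10, 10),
    translate_frac_x = stats::runif(1, -0.1, 0.1),
    translate_frac_y = stats::runif(1, -0.1, 0.1),
    shear_deg = stats::runif(1, -10, 10))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# 3x2 forward affine matrix (EBImage convention: out = [x y 1] %*% m),
# rotation+shear about the image center plus translation.
affine_matrix <- function(params, width, height) {
  th <- params$rotation_deg * pi / 180
  sh <- tan(params$shear_deg * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- S %*% R
  ctr <- c((width + 1) / 2, (height + 1) / 2)
  t_px <- c(params$translate_frac_x * width, params$translate_frac_y * height)
  off <- ctr - as.numeric(M %*% ctr) + t_px
  rbind(t(M), off)
}

#' Apply one geometric augmentation to an image/mask pair
#'
#' The identical affine transform (rotation and shear about the image
#' center, then translation) is applied to both. The image is resampled
#' bilinearly; the mask with nearest-neighbour so it stays binary.
#' Out-of-bounds pixels are filled with 0.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D binary matrix of the same shape (optional).
#' @param params an [augmentation_params()].
#' @return list with `image` and `mask` (the latter `NULL` if not supplied).
#' @export
augment <- function(image, mask = NULL, params) {
  stopifnot(inherits(params, "augmentation_params"))
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  if (params$rotation_deg == 0 && params$shear_deg == 0 &&
      params$translate_frac_x == 0 && params$translate_frac_y == 0)
    return(list(image = image, mask = mask))
  m <- affine_matrix(params, nrow(image), ncol(image))
  img_t <- EBImage::affine(image, m, filter = "bilinear", bg.col = 0)
  img_t <- matrix(as.numeric(EBImage::imageData(img_t)), nrow(image))
  msk_t <- NULL
  if (!is.null(mask)) {
    msk_t <- EBImage::affine(mask, m, filter = "none", bg.col = 0)
    msk_t <- matrix(as.numeric(EBImage::imageData(msk_t)) > 0.5,
                    nrow(mask)) * 1
  }
  list(image = img_t, mask = msk_t)
}

#' Split a dataset into training and validation parts
#'
#' Random, seeded, disjoint and exhaustive split; the training part holds
#' `round(train_frac * n)` items.
#'
#' @param items a list or vector of items (n >= 2).
#' @param train_frac fraction of items for training (default 0.8).
#' @param seed RNG seed for the permutation.
#' @return list with `train`, `val`, and the index vectors `train_idx`,
#'   `val_idx` into the original `items`.
#' @export
split_dataset <- function(items, train_frac = 0.8, seed = 1L) {
  n <- length(items)
  if (n < 2L) stop("need at least 2 items to split")
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)")
  n_train <- round(train_frac * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  val_idx <- sort(perm[(n_train + 1L):n])
  list(train = items[train_idx], val = items[val_idx],
       train_idx = train_idx, val_idx = val_idx)
}
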