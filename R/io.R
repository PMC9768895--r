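#' Write a volume or mask to NIfTI
#'
#' Masks carry their `zone_id` in the NIfTI header description field so the
#' label survives a round trip through disk.
#'
#' @param x a [pet_volume()] or [zone_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "pet_volume")) {
    vs <- x$voxel_size_mm
    descrip <- "pet_volume"
  } else if (inherits(x, "zone_mask")) {
    vs <- c(1, 1, 1)
    descrip <- x$zone_id
  } else stop("`x` must be a pet_volume or zone_mask")
  img <- RNifti::asNifti(x$data,
                         reference = list(pixdim = c(-1, vs, 0, 0, 0, 0),
                                          descrip = descrip))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a PET volume from NIfTI
#'
#' @param path NIfTI file.
#' @return A [pet_volume()] with voxel size taken from the header.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' Read a zone mask from NIfTI
#'
#' @param path NIfTI file written by [write_nifti_volume()].
#' @param zone_id optional label override; by default the header description.
#' @return A [zone_mask()].
#' @export
read_nifti_mask <- function(path, zone_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(zone_id)) {
    zone_id <- RNifti::niftiHeader(img)$descrip
    if (!nzchar(zone_id)) zone_id <- "unknown"
  }
  zone_mask(zone_id, array(as.numeric(img) > 0.5, dim(img)) * 1)
}

#' Write a 2D slice as PNG
#'
#' Grayscale by default; `palette = "spectrum"` renders with a blue-to-red
#' color scale of the kind used for clinical amyloid reads.
#'
#' @param slice 2D numeric matrix.
#' @param path output PNG path.
#' @param palette `"gray"` or `"spectrum"`.
#' @param range intensity window; defaults to the data range.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice, path, palette = c("gray", "spectrum"),
                            range = NULL) {
  palette <- match.arg(palette)
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG slices")
  if (is.null(range)) range <- base::range(slice)
  lo <- range[1]; hi <- range[2]
  z <- if (hi > lo) (slice - lo) / (hi - lo) else slice * 0
  z <- pmin(pmax(z, 0), 1)
  if (palette == "gray") {
    png::writePNG(t(z), path)  # writePNG expects rows = image rows
  } else {
    cols <- grDevices::col2rgb(
      grDevices::hcl.colors(256, "Spectral", rev = TRUE)) / 255
    idx <- pmin(pmax(1L + as.integer(z * 255), 1L), 256L)
    rgb <- array(0, c(ncol(slice), nrow(slice), 3))
    for (k in 1:3) rgb[, , k] <- t(matrix(cols[k, idx], nrow(slice)))
    png::writePNG(rgb, path)
  }
  invisible(path)
}

# phantom_spec <-> plain list (YAML-safe)
spec_to_list <- function(spec) {
  s <- unclass(spec)
  s$zones <- lapply(s$zones, unclass)
  s
}

list_to_spec <- function(lst) {
  zones <- lapply(lst$zones, function(z)
    zone_def(z$zone_id, z$geometry, positive = z$positive,
             uptake_ratio = z$uptake_ratio))
  phantom_spec(matrix_size = unlist(lst$matrix_size),
               voxel_size_mm = unlist(lst$voxel_size_mm),
               zones = zones,
               pons = lapply(lst$pons, unlist),
               background_region = lapply(lst$background_region,
                                          function(v) unlist(v)),
               background_uptake = lst$background_uptake,
               brain = if (is.null(lst$brain)) NULL
                       else lapply(lst$brain, unlist),
               noise_sigma = lst$noise_sigma,
               psf_fwhm_mm = lst$psf_fwhm_mm,
               seed = lst$seed)
}

#' Serialize a phantom spec to YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(spec_to_list(spec), path)
  invisible(path)
}

#' Read a phantom spec from YAML
#'
#' @param path YAML file written by [write_phantom_spec()].
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  list_to_spec(yaml::read_yaml(path))
}
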