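## io: multi-page TIFF stacks with YAML sidecar metadata.
##
## Image stacks travel as 32-bit float grayscale multi-page TIFF; grid
## metadata (z positions, pixel pitch, normalization) lives in a YAML
## sidecar next to the TIFF, since TIFF tags are not a reliable home for it.

sidecarPath <- function(path) paste0(path, ".yaml")

#' Read / write image stacks as multi-page TIFF
#'
#' `writeTiffStack` writes a 3D array (or matrix) as one 32-bit float page
#' per slice; `readTiffStack` reads it back as a 3D array. TIFF samples are
#' stored on [0, 1], so the data are min-max normalized on write and the
#' affine transform is returned (and recorded in sidecars) to undo it.
#'
#' @param path TIFF file path.
#' @param data numeric matrix or 3D array (v, u, z).
#' @return `writeTiffStack`: invisibly, list(offset, scale) such that
#'   `stored * scale + offset` restores the data. `readTiffStack`: a 3D
#'   numeric array (raw stored values unless offset/scale are supplied).
#' @export
writeTiffStack <- function(data, path) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  offset <- min(data)
  scale <- max(data) - offset
  if (scale == 0) scale <- 1
  norm <- (data - offset) / scale
  pages <- lapply(seq_len(dim(norm)[3]), function(k) norm[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(list(offset = offset, scale = scale))
}

#' @rdname writeTiffStack
#' @param offset,scale affine transform recorded at write time.
#' @export
readTiffStack <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr * scale + offset
}

#' Save / load a PSF stack (TIFF + YAML sidecar)
#'
#' @param psf a [PSFStack-class].
#' @param path TIFF path; metadata goes to `<path>.yaml`.
#' @return `loadPsfStack`: a [PSFStack-class].
#' @export
savePsfStack <- function(psf, path) {
  tr <- writeTiffStack(psf@data, path)
  yaml::write_yaml(list(
    type = "PSFStack",
    z_positions_um = psf@zPositionsUm,
    pixel_um = psf@pixelUm,
    normalization = psf@normalization,
    offset = tr$offset, scale = tr$scale), sidecarPath(path))
  invisible(path)
}

#' @rdname savePsfStack
#' @export
loadPsfStack <- function(path) {
  meta <- yaml::read_yaml(sidecarPath(path))
  d <- readTiffStack(path, offset = meta$offset %||% 0,
                     scale = meta$scale %||% 1)
  psfStack(pmax(d, 0),
           zPositionsUm = as.numeric(meta$z_positions_um),
           pixelUm = meta$pixel_um,
           normalization = meta$normalization)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a volume (TIFF + YAML sidecar)
#'
#' @param vol a [Volume-class].
#' @param path TIFF path; metadata goes to `<path>.yaml`.
#' @return `loadVolume`: a [Volume-class].
#' @export
saveVolume <- function(vol, path) {
  tr <- writeTiffStack(vol@data, path)
  yaml::write_yaml(list(
    type = "Volume",
    voxel_size_um = vol@voxelSizeUm,
    z_positions_um = vol@zPositionsUm,
    signed = vol@signed,
    offset = tr$offset, scale = tr$scale), sidecarPath(path))
  invisible(path)
}

#' @rdname saveVolume
#' @export
loadVolume <- function(path) {
  meta <- yaml::read_yaml(sidecarPath(path))
  d <- readTiffStack(path, offset = meta$offset %||% 0,
                     scale = meta$scale %||% 1)
  if (!isTRUE(meta$signed)) d <- pmax(d, 0)
  flfVolume(d, voxelSizeUm = as.numeric(meta$voxel_size_um),
            zPositionsUm = as.numeric(meta$z_positions_um),
            signed = isTRUE(meta$signed))
}

#' Read / write an optical configuration as YAML
#'
#' @param cfg an [OpticalConfig-class].
#' @param path YAML file path.
#' @return `readOpticalConfig`: an [OpticalConfig-class].
#' @export
writeOpticalConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    numerical_aperture = cfg@numericalAperture,
    magnification = cfg@magnification,
    excitation_wavelength_nm = cfg@excitationWavelengthNm,
    emission_wavelength_nm = cfg@emissionWavelengthNm,
    lenslet_grid = as.integer(cfg@lensletGrid),
    lenslet_occupancy_N = cfg@lensletOccupancyN,
    fourier_lens_focal_mm = cfg@fourierLensFocalMm,
    camera_pixel_um = cfg@cameraPixelUm,
    voxel_size_um = cfg@voxelSizeUm,
    z_range_um = cfg@zRangeUm,
    fov_um = cfg@fovUm), path)
  invisible(path)
}

#' @rdname writeOpticalConfig
#' @export
readOpticalConfig <- function(path) {
  m <- yaml::read_yaml(path)
  opticalConfig(
    numericalAperture = m$numerical_aperture,
    magnification = m$magnification,
    excitationWavelengthNm = m$excitation_wavelength_nm,
    emissionWavelengthNm = m$emission_wavelength_nm,
    lensletGrid = as.integer(unlist(m$lenslet_grid)),
    lensletOccupancyN = m$lenslet_occupancy_N,
    fourierLensFocalMm = m$fourier_lens_focal_mm,
    cameraPixelUm = m$camera_pixel_um,
    voxelSizeUm = as.numeric(unlist(m$voxel_size_um)),
    zRangeUm = as.numeric(unlist(m$z_range_um)),
    fovUm = as.numeric(unlist(m$fov_um)))
}

#' Export a spectrum and its fits
#'
#' Writes the spectrum as CSV (wavenumber, mean, sd, n) and, when fits are
#' supplied, the Lorentzian parameters as JSON next to it.
#'
#' @param spec an [FMIPSpectrum-class].
#' @param path CSV path.
#' @param fits optional data.frame from [fitLorentzian()]; written to
#'   `<path>.fits.json`.
#' @export
writeSpectrumCsv <- function(spec, path, fits = NULL) {
  utils::write.csv(data.frame(
    wavenumber_cm1 = spec@wavenumbersCm1,
    mean = spec@signal,
    sd = spec@signalSd,
    n = spec@nReplicates), path, row.names = FALSE)
  if (!is.null(fits))
    jsonlite::write_json(fits, paste0(path, ".fits.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
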