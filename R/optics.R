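## optics: depth-dependent light-field PSF simulation and bead calibration.
##
## The simulator is a geometric parallax model: each lenslet sees the scene
## from a distinct pupil offset, so a point source displaces laterally on
## that lenslet's elemental image at a rate proportional to the offset as it
## moves through focus, while the spot defocuses (widens) away from focus.
## This captures the two behaviors the reconstruction relies on — lateral
## parallax encoding depth, and defocus blur — without a wave-optics
## diffraction integral.

#' Lenslet geometry on the camera canvas
#'
#' Computes, for each lenslet of the grid, its elemental-image bounding box
#' and center on the composite canvas, its normalized pupil offset
#' (fraction of the pupil radius, from the occupancy ratio N), and its
#' parallax rate in micrometers of lateral image displacement per
#' micrometer of axial object displacement.
#'
#' The parallax rate is `NA * p` where `p` is the normalized pupil offset:
#' a marginal-ray view at the pupil edge displaces by NA micrometers per
#' micrometer of defocus (sine condition, object space).
#'
#' @param cfg an [OpticalConfig-class].
#' @param canvasPx canvas size in pixels, (v, u); defaults to the lenslet
#'   grid times the field of view in voxels.
#' @return data.frame with columns `row`, `col`, `centerV`, `centerU`,
#'   `pRow`, `pCol`, `rateVUmPerUm`, `rateUUmPerUm`, `v0`, `v1`, `u0`, `u1`.
#' @export
lensletLayout <- function(cfg, canvasPx = defaultCanvasPx(cfg)) {
  g <- cfg@lensletGrid
  hV <- canvasPx[1] %/% g[1]
  hU <- canvasPx[2] %/% g[2]
  if (hV < 1 || hU < 1)
    stop("lenslet grid exceeds canvas")
  out <- expand.grid(row = seq_len(g[1]), col = seq_len(g[2]))
  # normalized pupil offset (fraction of the pupil radius): lenslets tile
  # the pupil diameter in steps of diameter / N, centered on the axis, so
  # lenslet i sits at (i - (n+1)/2) * (diameter/N) = that many 2/N radii
  pOff <- function(i, n) (i - (n + 1) / 2) * (2 / cfg@lensletOccupancyN)
  out$pRow <- pOff(out$row, g[1])
  out$pCol <- pOff(out$col, g[2])
  out$centerV <- (out$row - 1) * hV + (hV + 1) / 2
  out$centerU <- (out$col - 1) * hU + (hU + 1) / 2
  out$rateVUmPerUm <- cfg@numericalAperture * out$pRow
  out$rateUUmPerUm <- cfg@numericalAperture * out$pCol
  out$v0 <- (out$row - 1L) * hV + 1L
  out$v1 <- out$row * hV
  out$u0 <- (out$col - 1L) * hU + 1L
  out$u1 <- out$col * hU
  out
}

defaultCanvasPx <- function(cfg) {
  dx <- cfg@voxelSizeUm[1]
  dy <- cfg@voxelSizeUm[2]
  c(cfg@lensletGrid[1] * round(cfg@fovUm[2] / dy),
    cfg@lensletGrid[2] * round(cfg@fovUm[1] / dx))
}

# in-focus spot sigma and defocus widening rate for the sub-aperture seen
# through one lenslet (effective NA = NA / N)
psfSpotParams <- function(cfg) {
  naEff <- cfg@numericalAperture / cfg@lensletOccupancyN
  lambdaUm <- cfg@emissionWavelengthNm / 1000
  fwhm0 <- 0.51 * lambdaUm / naEff
  list(sigma0Um = fwhm0 / (2 * sqrt(2 * log(2))),
       defocusRateUmPerUm = naEff / 2,
       naEff = naEff, lambdaUm = lambdaUm)
}

#' Simulate a depth-dependent light-field PSF stack
#'
#' Generates one composite-canvas PSF per axial position: each lenslet
#' contributes an elemental spot at its elemental-image center, displaced
#' laterally in proportion to depth (parallax) and widened away from focus
#' (defocus). The spot profile is Gaussian (default) or an Airy pattern.
#' Depths run over the configured z range at the axial voxel pitch.
#'
#' @param cfg an [OpticalConfig-class].
#' @param modelKind `"gaussian-parallax"` or `"airy-parallax"`.
#' @param canvasPx canvas (v, u) in pixels; default [lensletLayout()] sizing.
#' @param normalization PSF normalization (see [PSFStack-class]).
#' @param zStepUm axial sampling; defaults to the configured voxel dz.
#' @return a [PSFStack-class] sampled at the lateral voxel pitch.
#' @examples
#' cfg <- opticalConfig(fovUm = c(4.8, 4.8), zRangeUm = c(-1.05, 1.05))
#' psf <- simulatePsfStack(cfg)
#' psf
#' @export
simulatePsfStack <- function(cfg,
                             modelKind = c("gaussian-parallax",
                                           "airy-parallax"),
                             canvasPx = defaultCanvasPx(cfg),
                             normalization = "per-slice-sum-one",
                             zStepUm = cfg@voxelSizeUm[3]) {
  modelKind <- match.arg(modelKind)
  zs <- zGridUm(cfg@zRangeUm, zStepUm)
  if (length(zs) < 3)
    stop("z range must cover at least 3 slices")
  lay <- lensletLayout(cfg, canvasPx)
  sp <- psfSpotParams(cfg)
  pxUm <- cfg@voxelSizeUm[1]
  data <- array(0, dim = c(canvasPx[1], canvasPx[2], length(zs)))
  vv <- seq_len(canvasPx[1])
  uu <- seq_len(canvasPx[2])
  for (k in seq_along(zs)) {
    z <- zs[k]
    sigmaUm <- sqrt(sp$sigma0Um^2 + (sp$defocusRateUmPerUm * z)^2)
    slice <- matrix(0, canvasPx[1], canvasPx[2])
    for (l in seq_len(nrow(lay))) {
      cV <- lay$centerV[l] + lay$rateVUmPerUm[l] * z / pxUm
      cU <- lay$centerU[l] + lay$rateUUmPerUm[l] * z / pxUm
      slice <- slice + renderSpot(vv, uu, cV, cU, sigmaUm / pxUm,
                                  modelKind, sp, pxUm)
    }
    data[, , k] <- slice
  }
  normalizePsf(psfStack(data, zs, pxUm, normalization))
}

zGridUm <- function(zRangeUm, zStepUm) {
  if (diff(zRangeUm) <= 0) stop("z range has zero extent")
  nz <- floor(diff(zRangeUm) / zStepUm + 1e-9) + 1L
  zRangeUm[1] + zStepUm * (seq_len(nz) - 1)
}

renderSpot <- function(vv, uu, cV, cU, sigmaPx, modelKind, sp, pxUm) {
  dv <- vv - cV
  du <- uu - cU
  if (modelKind == "gaussian-parallax") {
    outer(exp(-dv^2 / (2 * sigmaPx^2)), exp(-du^2 / (2 * sigmaPx^2)))
  } else {
    # Airy pattern whose scale widens with defocus in step with the
    # Gaussian model (sigma ratio rescales the radial coordinate)
    r <- sqrt(outer(dv^2, du^2, `+`)) * pxUm
    scale <- sigmaPx * pxUm / sp$sigma0Um
    v <- 2 * pi * sp$naEff * r / (sp$lambdaUm * scale)
    a <- ifelse(v < 1e-8, 1, (2 * besselJ(pmax(v, 1e-8), 1) / pmax(v, 1e-8))^2)
    matrix(a, length(dv), length(du))
  }
}

normalizePsf <- function(psf) {
  d <- psf@data
  if (psf@normalization == "per-slice-sum-one") {
    for (k in seq_len(dim(d)[3])) {
      s <- sum(d[, , k])
      if (s > 0) d[, , k] <- d[, , k] / s
    }
  } else {
    m <- max(d)
    if (m > 0) d <- d / m
  }
  methods::initialize(psf, data = d)
}

#' Calibrate a PSF stack from a single-bead z-scan
#'
#' Turns a measured z-stack of one sub-resolution fluorescent bead into a
#' [PSFStack-class]: per slice, a percentile background floor is subtracted,
#' negative values are clipped to zero, and the stack is normalized. The
#' bead image centroid is recorded per slice.
#'
#' The stack must contain exactly one bead: at the best-focus slice each
#' elemental image is checked for a single connected bright region; more
#' than one signals a second bead in the field.
#'
#' @param stack numeric 3D array (v, u, z), one light-field image per depth.
#' @param cfg an [OpticalConfig-class] (for the lenslet grid).
#' @param zStepUm axial step of the scan in micrometers (default 0.1, a
#'   100 nm step).
#' @param zPositionsUm explicit axial positions; overrides `zStepUm`. The
#'   default centers the scan on z = 0.
#' @param pixelUm lateral pitch of the stack (default: lateral voxel size).
#' @param backgroundPercentile per-slice background floor (default 0.10).
#' @param normalization PSF normalization for the result.
#' @return a [PSFStack-class] with per-slice bead centroids.
#' @export
calibratePsfFromBeads <- function(stack, cfg,
                                  zStepUm = 0.1,
                                  zPositionsUm = NULL,
                                  pixelUm = cfg@voxelSizeUm[1],
                                  backgroundPercentile = 0.10,
                                  normalization = "per-slice-sum-one") {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a 3D array (v, u, z)")
  if (is.null(zPositionsUm))
    zPositionsUm <- (seq_len(d[3]) - (d[3] + 1) / 2) * zStepUm
  if (max(stack) <= min(stack))
    stop("no bead found: stack has no intensity structure")

  clean <- array(0, dim = d)
  centroids <- matrix(NA_real_, d[3], 2,
                      dimnames = list(NULL, c("v", "u")))
  for (k in seq_len(d[3])) {
    s <- stack[, , k]
    s <- pmax(s - stats::quantile(s, backgroundPercentile, names = FALSE), 0)
    clean[, , k] <- s
    tot <- sum(s)
    if (tot > 0) {
      centroids[k, ] <- c(sum(row(s) * s), sum(col(s) * s)) / tot
    }
  }
  if (max(clean) <= 0)
    stop("no bead found: nothing above the background floor")

  checkSingleBead(clean, cfg, d)

  normalizePsf(psfStack(clean, zPositionsUm, pixelUm, normalization,
                        beadCentroids = centroids))
}

# at the best-focus slice, each elemental image must contain at most one
# connected region above half its local maximum
checkSingleBead <- function(clean, cfg, d) {
  peakPerSlice <- apply(clean, 3, max)
  best <- clean[, , which.max(peakPerSlice)]
  lay <- lensletLayout(cfg, canvasPx = d[1:2])
  for (l in seq_len(nrow(lay))) {
    cell <- best[lay$v0[l]:lay$v1[l], lay$u0[l]:lay$u1[l]]
    m <- max(cell)
    if (m <= 0) next
    labs <- labelComponents3d(cell > 0.5 * m)
    if (max(labs) > 1)
      stop("ambiguous calibration stack: multiple beads detected in one ",
           "elemental image")
  }
  invisible(TRUE)
}
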