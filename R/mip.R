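## mip: mid-infrared photothermal signal extraction.
##
## One photothermal measurement is a pair of light-field frames taken with
## the mid-IR pump on and off. Heating at an absorbing vibrational band
## modulates the fluorescence of a thermosensitive dye (about 1% per
## Kelvin), so the IR-off minus IR-on difference carries the absorption
## contrast. Sign convention: positive difference = fluorescence decreased
## under IR heating. The difference is never clipped — display-side
## clipping is a downstream choice.

checkPairGeometry <- function(pair) {
  if (!identical(dim(pair@irOn@data), dim(pair@irOff@data)))
    stop("IR-on and IR-off frames have mismatched geometry")
  invisible(TRUE)
}

#' Photothermal difference frame (IR-off minus IR-on)
#'
#' Also logs (not corrects) a drift check: the integer cross-correlation
#' shift between the two frames, available as attribute `driftPx` on the
#' returned frame's data. A snapshot instrument should show < 0.5 px.
#'
#' @param pair a [FramePair-class].
#' @return a [LightFieldFrame-class] with tag `"diff"`; negative pixels are
#'   retained.
#' @export
fmipDifference <- function(pair) {
  checkPairGeometry(pair)
  d <- pair@irOff@data - pair@irOn@data
  drift <- crossCorrelationShift(pair@irOff@data, pair@irOn@data)
  if (max(abs(drift)) >= 0.5)
    warning("frame drift of (", drift[1], ", ", drift[2],
            ") px detected between IR-on and IR-off frames")
  out <- lightFieldFrame(d, elementalLayout = pair@irOff@elementalLayout,
                         exposureTag = "diff")
  attr(out@data, "driftPx") <- drift
  out
}

# integer image shift by FFT phase correlation (drift logging only)
crossCorrelationShift <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  xc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  m <- arrayInd(which.max(xc), dim(xc)) - 1L
  d <- dim(a)
  m <- ifelse(m > d / 2, m - d, m)
  as.numeric(m)
}

#' FMIP ratio map
#'
#' The photothermal signal normalized by the fluorescence baseline:
#' `(IR-off - IR-on) / max(IR-off, floor)`. Dimensionless; proportional to
#' the local mid-IR absorption at the pump wavenumber and invariant to a
#' global detector gain. Pixels whose IR-off intensity falls below the
#' floor are masked (NA).
#'
#' @param pair a [FramePair-class].
#' @param floor positive intensity guard for the division; default 1% of
#'   the IR-off frame's 99th-percentile intensity.
#' @return numeric matrix of ratios with NA at masked pixels.
#' @export
fmipRatio <- function(pair,
                      floor = 0.01 * stats::quantile(pair@irOff@data, 0.99,
                                                     names = FALSE)) {
  checkPairGeometry(pair)
  if (!is.finite(floor) || floor <= 0)
    stop("floor must be a positive intensity")
  off <- pair@irOff@data
  r <- (off - pair@irOn@data) / pmax(off, floor)
  r[off < floor] <- NA_real_
  r
}

#' Reconstruct a 3D FMIP volume from one frame pair
#'
#' Default mode `"diff-then-recon"`: deconvolve the IR-off minus IR-on
#' difference frame directly (one reconstruction per volume; this is what
#' makes the volume rate half the camera frame rate). The nonnegativity
#' constraint is applied after flipping the difference to its dominant
#' sign, and the result is flipped back. Mode `"recon-then-diff"`
#' reconstructs both frames and subtracts the volumes; for a noiseless,
#' unregularized, well-posed problem the two agree by linearity.
#'
#' @param pair a [FramePair-class].
#' @param psf the calibrated [PSFStack-class].
#' @param settings a [ReconSettings-class].
#' Because the photothermal difference is a small fraction of the raw
#' fluorescence (about 1% per Kelvin), each frame handed to the solver is
#' normalized to unit peak and the reconstruction rescaled afterwards, so
#' the regularization weights in `settings` always act relative to peak
#' signal regardless of detector gain or modulation depth.
#'
#' @param mode `"diff-then-recon"` (default) or `"recon-then-diff"`.
#' @return a signed [Volume-class] of FMIP signal.
#' @export
reconstructFmipVolume <- function(pair, psf, settings,
                                  mode = c("diff-then-recon",
                                           "recon-then-diff")) {
  mode <- match.arg(mode)
  checkPairGeometry(pair)
  zeroVolume <- function() {
    dps <- dim(psf@data)
    d <- dim(pair@irOff@data)
    dz <- if (length(psf@zPositionsUm) > 1) diff(psf@zPositionsUm)[1] else
      psf@pixelUm
    flfVolume(array(0, c(d[1] - dps[1] + 1, d[2] - dps[2] + 1, dps[3])),
              voxelSizeUm = c(psf@pixelUm, psf@pixelUm, dz),
              zPositionsUm = psf@zPositionsUm, signed = TRUE)
  }
  reconScaled <- function(data, tag, s) {
    res <- reconstruct(lightFieldFrame(data / s, exposureTag = tag),
                       psf, settings)
    v <- res@volume
    methods::initialize(v, data = s * v@data, signed = TRUE)
  }
  if (mode == "diff-then-recon") {
    diffFrame <- fmipDifference(pair)
    s <- max(abs(diffFrame@data))
    if (s == 0) return(zeroVolume())
    sgn <- if (sum(diffFrame@data) >= 0) 1 else -1
    v <- reconScaled(sgn * as.matrix(diffFrame@data), "diff", s)
    methods::initialize(v, data = sgn * v@data)
  } else {
    s <- max(pair@irOff@data)
    if (s == 0) return(zeroVolume())
    rOn <- reconScaled(pair@irOn@data, "plain", s)
    rOff <- reconScaled(pair@irOff@data, "plain", s)
    d <- rOff@data - rOn@data
    flfVolume(d, voxelSizeUm = rOff@voxelSizeUm,
              zPositionsUm = rOff@zPositionsUm, signed = TRUE)
  }
}
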