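## forward: the light-field image-formation operator and its adjoint.
##
## One camera frame is the axial sum of 2D *linear* convolutions between
## each object slice and the PSF slice at that depth. Zero-padded FFTs
## implement the convolution; the frame canvas is the full linear support
## (object + PSF - 1 per axis), so forward and adjoint are exact matrix
## transposes of one another — the property every ADMM step relies on.
## Circular convolution is deliberately avoided: wrap-around would leak
## signal between elemental images, which the instrument's iris prevents.

# Precompute padded FFTs of every PSF slice for a given object lateral size.
# Returns the operator context reused by applyForward / applyAdjoint.
psfOperator <- function(psf, ny, nx) {
  d <- dim(psf@data)
  outV <- ny + d[1] - 1L
  outU <- nx + d[2] - 1L
  M <- fastLen(outV)
  N <- fastLen(outU)
  Hf <- array(complex(real = 0), dim = c(M, N, d[3]))
  for (k in seq_len(d[3])) {
    pad <- matrix(0, M, N)
    pad[seq_len(d[1]), seq_len(d[2])] <- psf@data[, , k]
    Hf[, , k] <- stats::fft(pad)
  }
  list(Hf = Hf, M = M, N = N, ny = ny, nx = nx, nv = d[1], nu = d[2],
       outV = outV, outU = outU, nz = d[3])
}

# y = sum_z x_z (*) h_z, full linear support (outV x outU)
applyForward <- function(x, op) {
  acc <- matrix(complex(real = 0), op$M, op$N)
  pad <- matrix(0, op$M, op$N)
  for (k in seq_len(op$nz)) {
    pad[] <- 0
    pad[seq_len(op$ny), seq_len(op$nx)] <- x[, , k]
    acc <- acc + stats::fft(pad) * op$Hf[, , k]
  }
  y <- Re(stats::fft(acc, inverse = TRUE)) / (op$M * op$N)
  y[seq_len(op$outV), seq_len(op$outU), drop = FALSE]
}

# x_z = valid cross-correlation of y with h_z (exact transpose of forward)
applyAdjoint <- function(y, op) {
  pad <- matrix(0, op$M, op$N)
  pad[seq_len(op$outV), seq_len(op$outU)] <- y
  Yf <- stats::fft(pad)
  x <- array(0, dim = c(op$ny, op$nx, op$nz))
  for (k in seq_len(op$nz)) {
    full <- Re(stats::fft(Yf * Conj(op$Hf[, , k]), inverse = TRUE)) /
      (op$M * op$N)
    x[, , k] <- full[seq_len(op$ny), seq_len(op$nx)]
  }
  x
}

checkZGridsMatch <- function(volume, psf) {
  zv <- volume@zPositionsUm
  zp <- psf@zPositionsUm
  if (length(zv) != length(zp) || max(abs(zv - zp)) > 1e-6)
    stop("volume and PSF stack have mismatched z grids")
  invisible(TRUE)
}

#' @describeIn project Forward light-field projection: the frame is the
#'   axial sum of linear (zero-padded, non-circular) 2D convolutions of each
#'   object slice with its depth-matched PSF slice. The output canvas is the
#'   full convolution support. Under per-slice-sum-one PSF normalization the
#'   projection conserves total flux.
#' @param layout optional elemental-image bounding boxes for the output
#'   frame (see [frameLayout()]); empty when unspecified.
#' @param exposureTag tag for the output frame.
#' @export
setMethod("project", signature("Volume", "PSFStack"),
  function(volume, psf, layout = emptyLayout(), exposureTag = "plain") {
    checkZGridsMatch(volume, psf)
    x <- volume@data
    if (length(x) == 0) stop("empty volume")
    op <- psfOperator(psf, dim(x)[1], dim(x)[2])
    y <- applyForward(x, op)
    signed <- volume@signed || exposureTag == "diff"
    if (!signed) y <- pmax(y, 0)  # clip FFT round-off
    lightFieldFrame(y, elementalLayout = layout,
                    exposureTag = if (signed) "diff" else exposureTag)
  })

#' Elemental-image layout on a projected frame canvas
#'
#' The frame produced by [project()] is larger than the PSF canvas by the
#' object's lateral extent minus one per axis; each lenslet's elemental
#' bounding box shifts by half of that padding. This helper places the
#' configuration's lenslet boxes on the enlarged canvas.
#'
#' @param cfg an [OpticalConfig-class].
#' @param psfCanvasPx PSF canvas size (v, u) in pixels.
#' @param ny,nx lateral size of the projected volume.
#' @return a layout data.frame as used by [LightFieldFrame-class].
#' @export
frameLayout <- function(cfg, psfCanvasPx, ny, nx) {
  lay <- lensletLayout(cfg, canvasPx = psfCanvasPx)
  dv <- (ny - 1L) %/% 2L
  du <- (nx - 1L) %/% 2L
  lay$v0 <- lay$v0 + dv; lay$v1 <- lay$v1 + dv
  lay$u0 <- lay$u0 + du; lay$u1 <- lay$u1 + du
  lay$centerV <- lay$centerV + dv
  lay$centerU <- lay$centerU + du
  lay[c("row", "col", "centerV", "centerU", "v0", "v1", "u0", "u1")]
}

#' @describeIn adjointProject Transpose of [project()]: per depth, the valid
#'   cross-correlation of the frame with that depth's PSF slice. Satisfies
#'   the inner-product identity `<project(x), y> == <x, adjointProject(y)>`.
#' @param ny,nx lateral size of the target volume grid; defaults assume the
#'   frame canvas is the full convolution support of a volume matching the
#'   PSF canvas.
#' @export
setMethod("adjointProject", signature("LightFieldFrame", "PSFStack"),
  function(frame, psf,
           ny = nrow(frame@data) - dim(psf@data)[1] + 1L,
           nx = ncol(frame@data) - dim(psf@data)[2] + 1L) {
    if (ny < 1 || nx < 1)
      stop("frame canvas smaller than the PSF canvas: geometry mismatch")
    op <- psfOperator(psf, ny, nx)
    if (op$outV != nrow(frame@data) || op$outU != ncol(frame@data))
      stop("frame canvas does not match the projection geometry")
    x <- applyAdjoint(frame@data, op)
    dz <- if (length(psf@zPositionsUm) > 1) diff(psf@zPositionsUm)[1] else
      psf@pixelUm
    flfVolume(x, voxelSizeUm = c(psf@pixelUm, psf@pixelUm, dz),
              zPositionsUm = psf@zPositionsUm, signed = TRUE)
  })
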