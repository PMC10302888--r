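# Shared fixtures. Expensive objects (simulated PSF stacks, the end-to-end
# bead reconstruction) are built once per test run and cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# small instrument: 16x16 lateral voxels, 5 depths, 32x32 PSF canvas
smallConfig <- function() {
  opticalConfig(fovUm = c(4.8, 4.8), zRangeUm = c(-0.7, 0.7))
}

smallPsf <- function() {
  cached("smallPsf", function() simulatePsfStack(smallConfig()))
}

# mid-size instrument: 32x32 lateral voxels, 7 depths, 64x64 canvas
midConfig <- function() {
  opticalConfig(fovUm = c(9.6, 9.6), zRangeUm = c(-1.05, 1.05))
}

midPsf <- function() {
  cached("midPsf", function() simulatePsfStack(midConfig()))
}

# an unstructured random PSF stack: stresses operators harder than the
# smooth parallax model
randomPsf <- function(nv = 8, nu = 8, nz = 4, seed = 42) {
  set.seed(seed)
  d <- array(stats::runif(nv * nu * nz), dim = c(nv, nu, nz))
  for (k in seq_len(nz)) d[, , k] <- d[, , k] / sum(d[, , k])
  psfStack(d, zPositionsUm = (seq_len(nz) - (nz + 1) / 2) * 0.35,
           pixelUm = 0.3)
}

volumeOn <- function(data, psf, signed = FALSE) {
  dz <- if (length(psf@zPositionsUm) > 1) diff(psf@zPositionsUm)[1] else
    psf@pixelUm
  flfVolume(data, voxelSizeUm = c(psf@pixelUm, psf@pixelUm, dz),
            zPositionsUm = psf@zPositionsUm, signed = signed)
}

# brute-force forward projection: nested-loop linear convolution summed
# over depth (the independent oracle for the FFT path)
directProject <- function(x, psfData) {
  dx <- dim(x); dp <- dim(psfData)
  out <- matrix(0, dx[1] + dp[1] - 1, dx[2] + dp[2] - 1)
  for (k in seq_len(dx[3])) {
    for (i in seq_len(dx[1])) {
      for (j in seq_len(dx[2])) {
        v <- x[i, j, k]
        if (v != 0)
          out[i:(i + dp[1] - 1), j:(j + dp[2] - 1)] <-
            out[i:(i + dp[1] - 1), j:(j + dp[2] - 1)] + v * psfData[, , k]
      }
    }
  }
  out
}

# brute-force isotropic 3D TV with replicate boundary
directTv3d <- function(x) {
  d <- dim(x)
  tv <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    gy <- if (i < d[1]) x[i + 1, j, k] - x[i, j, k] else 0
    gx <- if (j < d[2]) x[i, j + 1, k] - x[i, j, k] else 0
    gz <- if (k < d[3]) x[i, j, k + 1] - x[i, j, k] else 0
    tv <- tv + sqrt(gx^2 + gy^2 + gz^2)
  }
  tv
}

relErr <- function(a, b) {
  den <- sqrt(sum(b^2))
  if (den == 0) sqrt(sum(a^2)) else sqrt(sum((a - b)^2)) / den
}

# centroid of one elemental box of a PSF slice
boxCentroid <- function(slice, box) {
  cell <- slice[box$v0:box$v1, box$u0:box$u1]
  tot <- sum(cell)
  c(v = box$v0 - 1 + sum(row(cell) * cell) / tot,
    u = box$u0 - 1 + sum(col(cell) * cell) / tot)
}

# the full instrument bead reconstruction shared by the resolution tests:
# paper-configuration optics, one sub-voxel bead at the volume center,
# noiseless projection, default ADMM settings
endToEndBeadRecon <- function() {
  cached("endToEndBeadRecon", function() {
    cfg <- opticalConfig()
    psf <- simulatePsfStack(cfg)
    spec <- phantomSpec(kind = "beads",
                        geometry = list(n = 1, positionsUm =
                                          matrix(c(-0.15, -0.15, 0), 1)),
                        photonBudget = 0)
    vols <- generateVolume(spec, cfg)
    frame <- project(vols$fluorescence, psf)
    frame <- lightFieldFrame(imageData(frame) / max(imageData(frame)))
    res <- reconstruct(frame, psf, reconSettings())
    list(res = res, truth = vols$positionsUm,
         report = resolutionReport(res@volume, vols$positionsUm))
  })
}
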