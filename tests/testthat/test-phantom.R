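test_that("a fixed seed reproduces the phantom byte for byte", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "cell-with-droplets",
                      geometry = list(cellRadiusUm = 3.5,
                                      nucleusRadiusUm = 1,
                                      nDroplets = 3,
                                      dropletRadiusRangeUm = c(0.5, 0.8)),
                      seed = 17)
  v1 <- generateVolume(spec, cfg)
  v2 <- generateVolume(spec, cfg)
  expect_identical(imageData(v1$fluorescence), imageData(v2$fluorescence))
  expect_identical(v1$positionsUm, v2$positionsUm)
  p1 <- generateFramePair(v1, psf, 1744, spec)
  p2 <- generateFramePair(v2, psf, 1744, spec)
  expect_identical(imageData(p1@irOn), imageData(p2@irOn))
  expect_identical(imageData(p1@irOff), imageData(p2@irOff))
})

test_that("a single centered bead grids to one bright voxel", {
  cfg <- midConfig()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 1,
                                      positionsUm = matrix(c(0, 0, 0), 1)))
  vols <- generateVolume(spec, cfg)
  x <- imageData(vols$fluorescence)
  expect_equal(sum(x > 0), 1L)
  expect_equal(sum(x), 1)
})

test_that("zero substrate tilt puts every rod centroid in one z plane", {
  cfg <- midConfig()
  spec <- phantomSpec(kind = "rods-on-tilted-substrate",
                      geometry = list(n = 5, tiltDeg = 0, lengthUm = 1.2,
                                      radiusUm = 0.3),
                      seed = 3)
  vols <- generateVolume(spec, cfg)
  expect_equal(unname(vols$positionsUm[, 3]), rep(0, 5))
  # nonzero tilt spreads the rods across depth
  spec2 <- phantomSpec(kind = "rods-on-tilted-substrate",
                       geometry = list(n = 5, tiltDeg = 15, lengthUm = 1.2,
                                       radiusUm = 0.3),
                       seed = 3)
  vols2 <- generateVolume(spec2, cfg)
  expect_gt(diff(range(vols2$positionsUm[, 3])), 0.2)
})

test_that("zero temperature rise leaves IR-on equal to IR-off", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 2, classes = "lipid"),
                      temperatureRiseK = 0, photonBudget = 0, seed = 2)
  vols <- generateVolume(spec, cfg)
  pair <- generateFramePair(vols, psf, 1744, spec)
  expect_identical(imageData(pair@irOn), imageData(pair@irOff))
})

test_that("off-band pumping is suppressed by the Lorentzian line shape", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 1,
                                      positionsUm = matrix(c(0, 0, 0), 1),
                                      classes = "lipid"),
                      photonBudget = 0)
  vols <- generateVolume(spec, cfg)
  atBand <- fmipRatio(generateFramePair(vols, psf, 1744, spec))
  offBand <- fmipRatio(generateFramePair(vols, psf, 1650, spec))
  bright <- which(!is.na(atBand) & atBand > 0.009)
  suppression <- offBand[bright] / atBand[bright]
  gamma <- 10
  expected <- gamma^2 / ((1650 - 1744)^2 + gamma^2)
  expect_lt(max(abs(suppression - expected)), 1e-10)
})

test_that("unphysical modulation is rejected", {
  cfg <- midConfig()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 1, classes = "lipid"),
                      temperatureRiseK = 200)
  vols <- generateVolume(spec, cfg)
  expect_error(modulationField(vols, 1744, spec), "unphysical")
})

test_that("bead calibration stacks are reproducible and faithful", {
  psf <- smallPsf()
  # noiseless: equals the PSF up to one global scale
  s0 <- generateBeadCalibrationStack(psf, photonBudget = 0)
  expect_lt(relErr(s0 / sum(s0), imageData(psf) / sum(imageData(psf))), 1e-12)
  s1 <- generateBeadCalibrationStack(psf, photonBudget = 5000, seed = 4)
  s2 <- generateBeadCalibrationStack(psf, photonBudget = 5000, seed = 4)
  expect_identical(s1, s2)
})

test_that("calibration centroids stay within 0.2 px at SNR 50", {
  cfg <- smallConfig()
  psf <- smallPsf()
  ref <- calibratePsfFromBeads(generateBeadCalibrationStack(psf, 0), cfg,
                               zStepUm = 0.35)
  k0 <- which.min(abs(zPositionsUm(psf)))
  errs <- vapply(1:20, function(i) {
    stack <- generateBeadCalibrationStack(psf, photonBudget = 2500,
                                          readNoiseSd = 1, seed = 100 + i)
    cal <- calibratePsfFromBeads(stack, cfg, zStepUm = 0.35)
    sqrt(sum((cal@beadCentroids[k0, ] - ref@beadCentroids[k0, ])^2))
  }, numeric(1))
  expect_lt(max(errs), 0.2)
})

test_that("null chemistry stays null through the whole pipeline", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 2, classes = "none"),
                      photonBudget = 0, seed = 6)
  vols <- generateVolume(spec, cfg)
  pair <- generateFramePair(vols, psf, 1744, spec)
  expect_identical(imageData(pair@irOn), imageData(pair@irOff))
  fmip <- reconstructFmipVolume(pair, psf,
                                reconSettings(maxIters = 15L,
                                              depthClipAxialFwhmMultiplier = 0))
  expect_lt(max(abs(imageData(fmip))), 1e-9)
})
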