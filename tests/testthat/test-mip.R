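pairFromMatrices <- function(off, on, wavenumber = 1744) {
  framePair(irOn = lightFieldFrame(on, exposureTag = "ir_on"),
            irOff = lightFieldFrame(off, exposureTag = "ir_off"),
            wavenumberCm1 = wavenumber)
}

test_that("fmipDifference subtracts IR-on from IR-off", {
  m <- matrix(5, 8, 8)
  expect_true(all(imageData(fmipDifference(pairFromMatrices(m, m))) == 0))
  d <- fmipDifference(pairFromMatrices(matrix(100, 8, 8), matrix(99, 8, 8)))
  expect_equal(unclass(imageData(d))[1:64], rep(1, 64))
  expect_identical(exposureTag(d), "diff")
})

test_that("fmipDifference is linear in both frames", {
  set.seed(8)
  off1 <- matrix(runif(64, 1, 2), 8); on1 <- matrix(runif(64, 0, 1), 8)
  off2 <- matrix(runif(64, 1, 2), 8); on2 <- matrix(runif(64, 0, 1), 8)
  a <- 2; b <- 3
  # random frames legitimately trip the drift logger; silence it here
  dc <- imageData(suppressWarnings(
    fmipDifference(pairFromMatrices(a * off1 + b * off2,
                                    a * on1 + b * on2))))
  ds <- a * imageData(suppressWarnings(
    fmipDifference(pairFromMatrices(off1, on1)))) +
    b * imageData(suppressWarnings(
      fmipDifference(pairFromMatrices(off2, on2))))
  expect_equal(as.vector(dc), as.vector(ds), tolerance = 1e-12)
})

test_that("fmipRatio computes the normalized modulation and masks dim pixels", {
  r <- fmipRatio(pairFromMatrices(matrix(200, 4, 4), matrix(198, 4, 4)),
                 floor = 1)
  expect_equal(r, matrix(0.01, 4, 4))
  same <- matrix(50, 4, 4)
  expect_equal(fmipRatio(pairFromMatrices(same, same), floor = 1),
               matrix(0, 4, 4))
  # gain invariance and masking
  off <- matrix(c(100, 100, 0.001, 100), 2)
  on <- off * 0.99
  r1 <- fmipRatio(pairFromMatrices(off, on), floor = 1)
  r2 <- fmipRatio(pairFromMatrices(10 * off, 10 * on), floor = 10)
  expect_true(is.na(r1[1, 2]))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(fmipRatio(pairFromMatrices(off, on), floor = 0),
               "positive")
})

test_that("the phantom's modulation depth is read back from the ratio map", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(n = 1,
                                      positionsUm = matrix(c(0, 0, 0), 1),
                                      classes = "lipid"),
                      photonBudget = 0)
  vols <- generateVolume(spec, cfg)
  pair <- generateFramePair(vols, psf, 1744, spec)
  r <- fmipRatio(pair)
  bright <- imageData(pair@irOff) >
    0.5 * max(imageData(pair@irOff))
  # pump at band center, 1%/K at 1 K: ratio = 0.01 on the object's image
  expect_equal(unname(r[bright]), rep(0.01, sum(bright)), tolerance = 1e-10)
})

test_that("only the modulated bead appears in the FMIP volume", {
  cfg <- midConfig()
  psf <- midPsf()
  spec <- phantomSpec(kind = "beads",
                      geometry = list(
                        n = 2,
                        positionsUm = rbind(c(-2.1, -2.1, -0.35),
                                            c(2.1, 2.1, 0.35)),
                        classes = c("lipid", "none")),
                      photonBudget = 0)
  vols <- generateVolume(spec, cfg)
  pair <- generateFramePair(vols, psf, 1744, spec)
  fmip <- reconstructFmipVolume(pair, psf,
                                reconSettings(maxIters = 40L,
                                              depthClipAxialFwhmMultiplier = 0))
  v <- imageData(fmip)
  g <- dim(v)
  near <- function(p) {
    i <- c(round(p[2] / 0.3 + (g[1] + 1) / 2),
           round(p[1] / 0.3 + (g[2] + 1) / 2),
           which.min(abs(zPositionsUm(fmip) - p[3])))
    max(abs(v[max(1, i[1] - 1):min(g[1], i[1] + 1),
              max(1, i[2] - 1):min(g[2], i[2] + 1),
              max(1, i[3] - 1):min(g[3], i[3] + 1)]))
  }
  modulated <- near(vols$positionsUm[1, ])
  unmodulated <- near(vols$positionsUm[2, ])
  expect_gt(modulated, 0)
  expect_lt(unmodulated, 0.1 * modulated)
})

test_that("diff-then-recon agrees with recon-then-diff when unregularized", {
  psf <- smallPsf()  # structured parallax PSF: well-conditioned depths
  set.seed(12)
  x <- array(0, c(12, 12, 5))
  x[sample(length(x), 4)] <- 1
  m <- array(0, dim(x)); m[x > 0] <- 0.01
  off <- project(volumeOn(x, psf), psf)
  on <- project(volumeOn(x * (1 - m), psf), psf)
  pair <- framePair(
    irOn = lightFieldFrame(imageData(on), exposureTag = "ir_on"),
    irOff = lightFieldFrame(imageData(off), exposureTag = "ir_off"),
    wavenumberCm1 = 1744)
  st <- reconSettings(lambdaL1 = 0, lambdaTv = 0, nonnegativity = FALSE,
                      maxIters = 300L, relTol = 1e-11,
                      depthClipAxialFwhmMultiplier = 0)
  v1 <- reconstructFmipVolume(pair, psf, st, mode = "diff-then-recon")
  v2 <- reconstructFmipVolume(pair, psf, st, mode = "recon-then-diff")
  expect_lt(relErr(imageData(v1), imageData(v2)), 0.05)
})

test_that("zero modulation gives a null FMIP volume", {
  psf <- randomPsf(8, 8, 3)
  set.seed(13)
  x <- array(stats::runif(10 * 10 * 3), c(10, 10, 3))
  off <- project(volumeOn(x, psf), psf)
  pair <- framePair(
    irOn = lightFieldFrame(imageData(off), exposureTag = "ir_on"),
    irOff = lightFieldFrame(imageData(off), exposureTag = "ir_off"),
    wavenumberCm1 = 1650)
  fmip <- reconstructFmipVolume(pair, psf,
                                reconSettings(maxIters = 20L,
                                              depthClipAxialFwhmMultiplier = 0))
  expect_lt(max(abs(imageData(fmip))), 1e-9)
})
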