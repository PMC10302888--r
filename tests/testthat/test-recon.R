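test_that("tv3d matches closed forms and the brute-force oracle", {
  expect_equal(tv3d(array(3.7, c(4, 4, 4))), 0)
  step <- array(0, c(2, 1, 1)); step[2, 1, 1] <- 1
  expect_equal(tv3d(step), 1)
  set.seed(21)
  x <- array(stats::rnorm(64), c(4, 4, 4))
  expect_equal(tv3d(x), directTv3d(x))
})

test_that("unregularized least squares recovers a well-posed single-slice object", {
  # a broadband (random) single-slice kernel keeps the problem well-posed
  psf <- randomPsf(5, 5, 1, seed = 19)
  set.seed(5)
  x <- array(stats::runif(12 * 12), c(12, 12, 1))
  frame <- project(volumeOn(x, psf), psf)
  res <- reconstruct(frame, psf,
                     reconSettings(lambdaL1 = 0, lambdaTv = 0,
                                   nonnegativity = FALSE, maxIters = 400L,
                                   relTol = 1e-12,
                                   depthClipAxialFwhmMultiplier = 0))
  expect_lt(relErr(imageData(res@volume), x), 1e-4)
})

test_that("sparse prior recovers isolated point sources without spurious peaks", {
  cfg <- opticalConfig(fovUm = c(19.2, 19.2), zRangeUm = c(-1.225, 1.225))
  # default canvas: the object fits one elemental pitch, as the iris enforces
  psf <- simulatePsfStack(cfg)
  spec <- phantomSpec(kind = "beads", geometry = list(n = 5), seed = 9,
                      photonBudget = 0)
  vols <- generateVolume(spec, cfg)
  x <- imageData(vols$fluorescence)
  expect_equal(dim(x), c(64L, 64L, 8L))
  frame <- project(vols$fluorescence, psf)
  frame <- lightFieldFrame(imageData(frame) / max(imageData(frame)))
  res <- reconstruct(frame, psf,
                     reconSettings(maxIters = 40L,
                                   depthClipAxialFwhmMultiplier = 0))
  r <- imageData(res@volume)
  trueIdx <- which(x > 0, arr.ind = TRUE)
  peakVals <- numeric(nrow(trueIdx))
  for (i in seq_len(nrow(trueIdx))) {
    p <- trueIdx[i, ]
    nb <- r[max(1, p[1] - 1):min(64, p[1] + 1),
            max(1, p[2] - 1):min(64, p[2] + 1),
            max(1, p[3] - 1):min(8, p[3] + 1)]
    peakVals[i] <- max(nb)
    # the local maximum must sit within 1 voxel of the true source
    expect_gt(max(nb), 0)
  }
  # no spurious peak above 10% of the weakest true peak
  mask <- array(TRUE, dim(r))
  for (i in seq_len(nrow(trueIdx))) {
    p <- trueIdx[i, ]
    mask[max(1, p[1] - 2):min(64, p[1] + 2),
         max(1, p[2] - 2):min(64, p[2] + 2),
         max(1, p[3] - 2):min(8, p[3] + 2)] <- FALSE
  }
  expect_lt(max(r[mask]), 0.1 * min(peakVals))
})

test_that("ADMM merged objective is non-increasing after burn-in", {
  psf <- randomPsf(8, 8, 3)
  for (seed in 1:3) {
    set.seed(seed)
    x <- array(0, c(12, 12, 3))
    x[sample(length(x), 6)] <- stats::runif(6, 0.5, 1)
    frame <- project(volumeOn(x, psf), psf)
    res <- reconstruct(frame, psf,
                       reconSettings(maxIters = 30L,
                                     depthClipAxialFwhmMultiplier = 0))
    tr <- res@objectiveTrace
    if (length(tr) > 6) {
      inc <- diff(tr[-(1:5)])
      expect_lte(max(inc), 1e-9 * abs(tr[6]))
    }
  }
})

test_that("data fidelity at convergence is monotone in the l1 weight", {
  psf <- randomPsf(8, 8, 3)
  set.seed(2)
  x <- array(0, c(10, 10, 3))
  x[sample(length(x), 5)] <- 1
  frame <- project(volumeOn(x, psf), psf)
  y <- imageData(frame)
  fid <- vapply(c(0, 1e-3, 1e-2), function(l1) {
    res <- reconstruct(frame, psf,
                       reconSettings(lambdaL1 = l1, lambdaTv = 0,
                                     maxIters = 80L,
                                     depthClipAxialFwhmMultiplier = 0))
    yhat <- imageData(project(res@volume, psf))
    0.5 * sum((yhat - y)^2)
  }, numeric(1))
  expect_true(all(diff(fid) >= -1e-10))
})

test_that("reconstruction is scaling-equivariant", {
  psf <- randomPsf(8, 8, 3)
  set.seed(4)
  x <- array(0, c(10, 10, 3))
  x[sample(length(x), 4)] <- 1
  frame <- project(volumeOn(x, psf), psf)
  cscale <- 7.3
  s1 <- reconSettings(lambdaL1 = 1e-3, lambdaTv = 2e-4, maxIters = 25L,
                      relTol = 1e-15, depthClipAxialFwhmMultiplier = 0)
  s2 <- reconSettings(lambdaL1 = cscale * 1e-3, lambdaTv = cscale * 2e-4,
                      maxIters = 25L, relTol = 1e-15,
                      depthClipAxialFwhmMultiplier = 0)
  r1 <- reconstruct(frame, psf, s1)
  r2 <- reconstruct(lightFieldFrame(cscale * imageData(frame)), psf, s2)
  expect_lt(relErr(imageData(r2@volume), cscale * imageData(r1@volume)),
            1e-6)
})

test_that("bead centroids are recovered to sub-voxel accuracy", {
  run <- endToEndBeadRecon()
  b <- run$report$beads
  expect_lt(abs(b$xUm - run$truth[1]), 0.5 * 0.3)
  expect_lt(abs(b$yUm - run$truth[2]), 0.5 * 0.3)
  expect_lt(abs(b$zUm - run$truth[3]), 1 * 0.35)
})

test_that("invalid measurements are rejected", {
  psf <- randomPsf()
  bad <- matrix(1, 16, 16); bad[3, 3] <- NaN
  expect_error(
    reconstruct(lightFieldFrame(bad), psf, reconSettings()),
    "NaN")
})
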