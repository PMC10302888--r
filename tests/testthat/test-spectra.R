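sixWavenumbers <- c(1690, 1701, 1712, 1723, 1734, 1745)

lorentzSpec <- function(nu, center, hwhm = 10, A = 0.01, b = 0.002,
                        noiseSd = 0, seed = NULL) {
  y <- A * hwhm^2 / ((nu - center)^2 + hwhm^2) + b
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(nu), 0, noiseSd)
  }
  fmipSpectrum(nu, y)
}

analyticVolume <- function(value, dims = c(4, 4, 3)) {
  flfVolume(array(value, dims), c(0.3, 0.3, 0.35),
            zPositionsUm = (seq_len(dims[3]) - 2) * 0.35, signed = TRUE)
}

test_that("extractSpectrum averages the ROI and handles replicates", {
  vols <- lapply(c(0.01, 0.02, 0.03), analyticVolume)
  roi <- array(FALSE, c(4, 4, 3)); roi[2, 3, 1] <- TRUE
  sp <- extractSpectrum(c(1700, 1720, 1740), vols, roi)
  expect_equal(spectrumSignal(sp), c(0.01, 0.02, 0.03))
  expect_true(all(is.na(spectrumSd(sp))))

  # three identical replicates: SD identically zero
  sp3 <- extractSpectrum(c(1700, 1720, 1740), list(vols, vols, vols), roi)
  expect_equal(spectrumSd(sp3), c(0, 0, 0))
  expect_equal(sp3@nReplicates, 3L)

  expect_error(extractSpectrum(c(1700, 1700, 1740), vols, roi), "duplicate")
  expect_error(extractSpectrum(c(1700, 1720, 1740), vols,
                               array(FALSE, c(4, 4, 3))), "empty ROI")
})

test_that("the spectrum peaks at the sampled wavenumber nearest the band", {
  # voxel values follow the 1744 line shape exactly
  vols <- lapply(sixWavenumbers, function(nu)
    analyticVolume(0.01 * flfmip:::lorentzianLine(nu, 1744, 10)))
  roi <- array(TRUE, c(4, 4, 3))
  sp <- extractSpectrum(sixWavenumbers, vols, roi)
  expect_equal(wavenumbersCm1(sp)[which.max(spectrumSignal(sp))],
               sixWavenumbers[which.min(abs(sixWavenumbers - 1744))])
})

test_that("Lorentzian fit recovers exact-model six-point spectra", {
  for (center in c(1744, 1704)) {
    fit <- fitLorentzian(lorentzSpec(sixWavenumbers, center))
    expect_true(fit$converged)
    expect_lt(abs(fit$centerCm1 - center), 0.1)
    expect_equal(fit$hwhmCm1, 10, tolerance = 1e-4)
    expect_equal(fit$amplitude, 0.01, tolerance = 1e-4)
    expect_equal(fit$baseline, 0.002, tolerance = 1e-4)
    expect_true(fit$centerReliable)
  }
})

test_that("a flat spectrum yields near-zero amplitude flagged unreliable", {
  flat <- fmipSpectrum(sixWavenumbers, rep(0.002, 6))
  fit <- fitLorentzian(flat)
  expect_lt(abs(fit$amplitude), 1e-6)
  expect_false(fit$centerReliable)
})

test_that("underdetermined fits are rejected", {
  sp <- fmipSpectrum(c(1700, 1720, 1740), c(0.01, 0.02, 0.01))
  expect_error(fitLorentzian(sp), "underdetermined")
  expect_error(fitLorentzian(lorentzSpec(sixWavenumbers, 1720),
                             nComponents = 2), "underdetermined")
})

test_that("center recovery stays unbiased under noise at SNR 10", {
  # 100 Monte-Carlo draws per band at amplitude/noise = 10
  noiseSd <- 0.001
  centers44 <- numeric(100)
  centers04 <- numeric(100)
  set.seed(99)
  for (i in 1:100) {
    centers44[i] <- fitLorentzian(
      lorentzSpec(sixWavenumbers, 1744, noiseSd = noiseSd))$centerCm1
    centers04[i] <- fitLorentzian(
      lorentzSpec(sixWavenumbers, 1704, noiseSd = noiseSd))$centerCm1
  }
  expect_lt(abs(mean(centers44) - 1744), 1)
  expect_lt(abs(mean(centers04) - 1704), 1)
  # the isotope separation is reproduced
  expect_lt(abs((mean(centers44) - mean(centers04)) - 40), 2)
})

test_that("peakRatio handles identity, zero and closed-form mixtures", {
  v <- analyticVolume(0.01, c(6, 6, 4))
  expect_equal(peakRatio(v, v)$ratio, 1)
  z <- analyticVolume(0, c(6, 6, 4))
  expect_equal(peakRatio(z, v)$ratio, 0)
  expect_error(peakRatio(v, z), "not positive")

  # half the droplet voxels isotope-shifted, equal band amplitudes,
  # evaluated exactly at the two band centers: the ratio follows from the
  # two line shapes in closed form
  L <- flfmip:::lorentzianLine
  dims <- c(6, 6, 4)
  labeled <- array(rep(c(TRUE, FALSE), length.out = prod(dims)), dims)
  v1704 <- array(0.01 * ifelse(labeled, L(1704, 1704, 10), L(1704, 1744, 10)),
                 dims)
  v1744 <- array(0.01 * ifelse(labeled, L(1744, 1704, 10), L(1744, 1744, 10)),
                 dims)
  expected <- mean(v1704) / mean(v1744)
  byHand <- (1 + L(1704, 1744, 10)) / (1 + L(1744, 1704, 10))
  expect_equal(expected, byHand, tolerance = 1e-12)
  r <- peakRatio(flfVolume(v1704, c(0.3, 0.3, 0.35), (1:4) * 0.35),
                 flfVolume(v1744, c(0.3, 0.3, 0.35), (1:4) * 0.35))
  expect_equal(r$ratio, expected, tolerance = 1e-12)

  # common gain leaves the ratio unchanged
  r10 <- peakRatio(flfVolume(10 * v1704, c(0.3, 0.3, 0.35), (1:4) * 0.35),
                   flfVolume(10 * v1744, c(0.3, 0.3, 0.35), (1:4) * 0.35))
  expect_equal(r10$ratio, r$ratio, tolerance = 1e-12)
})

test_that("per-droplet ratios are segmented from the denominator volume", {
  dims <- c(12, 12, 5)
  a <- array(0, dims); b <- array(0, dims)
  # two droplets with different isotope fractions
  b[3:5, 3:5, 2:3] <- 1; a[3:5, 3:5, 2:3] <- 0.8
  b[8:10, 8:10, 3:4] <- 1; a[8:10, 8:10, 3:4] <- 0.2
  r <- peakRatio(flfVolume(a, c(0.3, 0.3, 0.35), (1:5) * 0.35),
                 flfVolume(b, c(0.3, 0.3, 0.35), (1:5) * 0.35))
  expect_equal(nrow(r$perDroplet), 2)
  expect_equal(sort(r$perDroplet$ratio), c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(r$summary$mean, 0.5, tolerance = 1e-12)
  expect_equal(r$summary$min, 0.2, tolerance = 1e-12)
  expect_equal(r$summary$max, 0.8, tolerance = 1e-12)
})
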