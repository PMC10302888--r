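## metrics: resolution characterization and physical scales.

#' Thermal diffusivity of water at room temperature (m^2/s)
#'
#' Documented default for [thermalDiffusionLength()]; biological specimens
#' are water-dominated on the scale of a photothermal pump pulse.
#' @export
waterThermalDiffusivityM2s <- 1.38e-7

# internal: least-squares Gaussian fit y = A exp(-(x - c)^2 / (2 s^2)) + b
gaussianProfileFit <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 4)
  b0 <- min(y)
  a0 <- max(y) - b0
  c0 <- x[which.max(y)]
  above <- y - b0 >= a0 / 2
  s0 <- max(diff(range(x[above])), diff(range(x)) / length(x)) /
    (2 * sqrt(2 * log(2)))
  df <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - cc)^2 / (2 * s^2)) + b,
    data = df,
    start = list(A = a0, cc = c0, s = s0, b = b0),
    lower = c(0, min(x) - diff(range(x)), 1e-9, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  tss <- sum((y - mean(y))^2)
  list(amplitude = unname(co["A"]), center = unname(co["cc"]),
       sigma = unname(co["s"]), offset = unname(co["b"]),
       fwhm = 2 * sqrt(2 * log(2)) * unname(co["s"]),
       r2 = if (tss > 0) 1 - sum(res^2) / tss else NA_real_)
}

#' Gaussian-fit full width at half maximum of a 1D intensity profile
#'
#' Fits amplitude, center, width and constant offset by nonlinear least
#' squares and returns `FWHM = 2 sqrt(2 ln 2) * sigma` in micrometers.
#' The estimate is invariant to intensity scaling and constant offsets.
#'
#' @param profile numeric intensity samples (>= 5, single dominant peak).
#' @param spacingUm sample spacing in micrometers.
#' @return FWHM in micrometers, with attributes `fit` (the full parameter
#'   list) and `multimodal` (TRUE when more than one well-separated peak
#'   exceeds half maximum, in which case a warning is issued).
#' @examples
#' x <- seq(-3, 3, by = 0.1)
#' p <- exp(-x^2 / (2 * 0.3^2))
#' fwhmGaussian(p, 0.1)  # 2*sqrt(2*log(2))*0.3 = 0.7064
#' @export
fwhmGaussian <- function(profile, spacingUm) {
  if (length(profile) < 5) stop("need at least 5 samples")
  if (max(profile) - min(profile) <= 0)
    stop("no peak: profile is flat")
  x <- (seq_along(profile) - 1) * spacingUm
  # peak must rise credibly above the baseline
  base <- stats::median(profile)
  if (max(profile) - base <= 1e-3 * max(abs(profile), 1e-300))
    stop("no peak: maximum does not rise above the baseline")
  fit <- gaussianProfileFit(profile, x)

  half <- fit$offset + (max(profile) - fit$offset) / 2
  above <- profile > half
  nRuns <- sum(diff(c(FALSE, above)) == 1)
  multimodal <- nRuns > 1
  if (multimodal)
    warning("profile looks multimodal: ", nRuns,
            " separate regions exceed half maximum")
  structure(fit$fwhm, fit = fit, multimodal = multimodal)
}

#' Resolution report for a reconstructed bead volume
#'
#' For each ground-truth bead position, locates the nearby intensity
#' maximum (with sub-voxel quadratic peak interpolation), extracts the x, y
#' and z line profiles through it, Gaussian-fits each, and aggregates
#' lateral and axial FWHMs. Beads closer to one another than
#' `minSeparationUm` are flagged as overlapping and excluded.
#'
#' Ground-truth positions use the volume's physical frame: lateral
#' coordinates in micrometers relative to the volume center, z as absolute
#' slice positions.
#'
#' @param recon a reconstructed [Volume-class].
#' @param truthPositionsUm matrix with columns x, y, z (um), one bead per row.
#' @param searchRadiusUm radius around each truth position searched for the
#'   reconstructed maximum (default 1 um).
#' @param minSeparationUm overlap-exclusion distance (default 3 x an
#'   expected 0.7 um FWHM).
#' @return list with `beads` (data.frame: positions, per-axis FWHM um,
#'   fit R^2, `excluded` flag) and `summary` (min/max lateral and axial
#'   FWHM over retained beads).
#' @export
resolutionReport <- function(recon, truthPositionsUm,
                             searchRadiusUm = 1,
                             minSeparationUm = 3 * 0.7) {
  truthPositionsUm <- rbind(truthPositionsUm)
  n <- nrow(truthPositionsUm)
  if (n < 1) stop("need at least one bead")
  dat <- recon@data
  d <- dim(dat)
  vs <- recon@voxelSizeUm
  zs <- recon@zPositionsUm

  excluded <- rep(FALSE, n)
  if (n > 1) {
    dd <- as.matrix(stats::dist(truthPositionsUm))
    diag(dd) <- Inf
    excluded <- apply(dd, 1, min) < minSeparationUm
    if (any(excluded))
      warning(sum(excluded), " bead(s) excluded: closer than ",
              minSeparationUm, " um to a neighbor")
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- truthPositionsUm[i, ]
    ix <- round(p[1] / vs[1] + (d[2] + 1) / 2)
    iy <- round(p[2] / vs[2] + (d[1] + 1) / 2)
    iz <- which.min(abs(zs - p[3]))
    if (excluded[i]) {
      rows[[i]] <- data.frame(xUm = p[1], yUm = p[2], zUm = p[3],
                              fwhmXUm = NA, fwhmYUm = NA, fwhmZUm = NA,
                              r2X = NA, r2Y = NA, r2Z = NA, excluded = TRUE)
      next
    }
    # local max within the search radius
    rx <- max(1L, round(searchRadiusUm / vs[1]))
    ry <- max(1L, round(searchRadiusUm / vs[2]))
    rz <- max(1L, round(searchRadiusUm / vs[3]))
    xs <- max(1, ix - rx):min(d[2], ix + rx)
    ys <- max(1, iy - ry):min(d[1], iy + ry)
    zw <- max(1, iz - rz):min(d[3], iz + rz)
    sub <- dat[ys, xs, zw, drop = FALSE]
    m <- arrayInd(which.max(sub), dim(sub))
    iy <- ys[m[1]]; ix <- xs[m[2]]; iz <- zw[m[3]]

    # sub-voxel peak refinement
    offx <- if (ix > 1 && ix < d[2])
      quadraticPeakOffset(dat[iy, ix - 1, iz], dat[iy, ix, iz],
                          dat[iy, ix + 1, iz]) else 0
    offy <- if (iy > 1 && iy < d[1])
      quadraticPeakOffset(dat[iy - 1, ix, iz], dat[iy, ix, iz],
                          dat[iy + 1, ix, iz]) else 0
    offz <- if (iz > 1 && iz < d[3])
      quadraticPeakOffset(dat[iy, ix, iz - 1], dat[iy, ix, iz],
                          dat[iy, ix, iz + 1]) else 0

    fitAxis <- function(profile, spacing) {
      tryCatch({
        f <- fwhmGaussian(profile, spacing)
        c(as.numeric(f), attr(f, "fit")$r2)
      }, error = function(e) c(NA_real_, NA_real_))
    }
    fx <- fitAxis(dat[iy, , iz], vs[1])
    fy <- fitAxis(dat[, ix, iz], vs[2])
    fz <- fitAxis(dat[iy, ix, ], vs[3])

    rows[[i]] <- data.frame(
      xUm = (ix + offx - (d[2] + 1) / 2) * vs[1],
      yUm = (iy + offy - (d[1] + 1) / 2) * vs[2],
      zUm = zs[iz] + offz * vs[3],
      fwhmXUm = fx[1], fwhmYUm = fy[1], fwhmZUm = fz[1],
      r2X = fx[2], r2Y = fy[2], r2Z = fz[2],
      excluded = FALSE)
  }
  beads <- do.call(rbind, rows)
  keep <- beads[!beads$excluded, , drop = FALSE]
  lateral <- c(keep$fwhmXUm, keep$fwhmYUm)
  safeRange <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) range(v) else c(NA_real_, NA_real_)
  }
  list(beads = beads,
       summary = list(
         lateralFwhmUm = safeRange(lateral),
         axialFwhmUm = safeRange(keep$fwhmZUm),
         nBeads = nrow(keep)))
}

#' Thermal diffusion length of a photothermal pump pulse
#'
#' `L = sqrt(4 D tau)`: how far heat spreads during one pump pulse of
#' duration `tau`. With a 50 ns pulse and water-like diffusivity this is
#' about 165 nm — well below optical resolution, so photothermal heating
#' does not blur the image.
#'
#' @param pulseS pulse duration in seconds (>= 0).
#' @param diffusivityM2s thermal diffusivity in m^2/s (default: water).
#' @return diffusion length in meters.
#' @examples
#' thermalDiffusionLength(50e-9) * 1e9  # ~166 nm
#' @export
thermalDiffusionLength <- function(pulseS,
                                   diffusivityM2s = waterThermalDiffusivityM2s) {
  if (pulseS < 0) stop("pulse duration must be nonnegative")
  if (diffusivityM2s <= 0) stop("diffusivity must be positive")
  sqrt(4 * diffusivityM2s * pulseS)
}
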