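## spectra: FMIP spectra, Lorentzian fits, isotope peak ratios.
##
## The pump laser is stepped over a handful of wavenumbers (photobleaching
## limits sampling to about six points per cell), an FMIP volume is
## reconstructed at each, and the ROI-mean signal versus wavenumber is the
## FMIP spectrum. A Lorentzian line shape with a constant baseline (water
## absorption inside cells) is fitted to locate the vibrational band.

#' Extract an FMIP spectrum from multi-wavenumber volumes
#'
#' Per wavenumber, the mean FMIP voxel value over the ROI. When replicate
#' volume sets are supplied (e.g. N = 3 cells), the point is the mean of
#' the replicate ROI means and the error bar their standard deviation.
#'
#' @param wavenumbersCm1 pump wavenumbers, one per volume (must be unique;
#'   any order — the spectrum is sorted).
#' @param volumes list of [Volume-class], parallel to `wavenumbersCm1`, or
#'   a list of such lists (one per replicate).
#' @param roi logical/0-1 array matching the volume grid; voxels to average.
#' @return an [FMIPSpectrum-class].
#' @export
extractSpectrum <- function(wavenumbersCm1, volumes, roi) {
  if (anyDuplicated(wavenumbersCm1))
    stop("duplicate wavenumbers; supply replicates as a list of volume lists")
  if (length(wavenumbersCm1) < 3)
    stop("need at least 3 wavenumbers")
  reps <- if (methods::is(volumes[[1]], "Volume")) list(volumes) else volumes
  roi <- as.logical(roi)
  if (!any(roi)) stop("empty ROI")
  perRep <- sapply(reps, function(rep) {
    if (length(rep) != length(wavenumbersCm1))
      stop("each replicate needs one volume per wavenumber")
    vapply(rep, function(v) mean(v@data[roi]), numeric(1))
  })
  perRep <- matrix(perRep, nrow = length(wavenumbersCm1))
  ord <- order(wavenumbersCm1)
  nRep <- ncol(perRep)
  fmipSpectrum(
    wavenumbersCm1 = wavenumbersCm1[ord],
    signal = rowMeans(perRep)[ord],
    signalSd = if (nRep > 1) apply(perRep, 1, stats::sd)[ord]
               else rep(NA_real_, length(ord)),
    nReplicates = nRep)
}

#' Fit Lorentzian line shapes to an FMIP spectrum
#'
#' Nonlinear least squares of
#' `signal = sum_i A_i g_i^2 / ((nu - nu0_i)^2 + g_i^2) + baseline`,
#' with a constant (default) or linear baseline. Amplitudes are constrained
#' nonnegative (absorption bands are positive-going in the off-minus-on
#' convention) and widths to a physically sensible range, which keeps sparse
#' noisy spectra from collapsing onto inverted-peak local optima. Initialization is
#' multistart: a grid of 5 candidate centers spanning the sampled range
#' guards against local minima with sparse (six-point) sampling; the best
#' converged start by residual sum of squares wins.
#'
#' With six photobleaching-limited points a single component is the
#' default; two components need at least 8 points.
#'
#' @param spec an [FMIPSpectrum-class].
#' @param nComponents 1 or 2 Lorentzian components.
#' @param baseline `"constant"` or `"linear"`.
#' @return data.frame, one row per component (sorted by center): columns
#'   `centerCm1`, `hwhmCm1`, `amplitude`, `baseline`, `baselineSlope`,
#'   `rss`, `seCenter`, `converged`, `centerReliable`. `centerReliable` is
#'   FALSE when the amplitude is indistinguishable from the residual noise
#'   (flat spectrum: the center is meaningless).
#' @export
fitLorentzian <- function(spec, nComponents = 1, baseline = "constant") {
  baseline <- match.arg(baseline, c("constant", "linear"))
  nu <- spec@wavenumbersCm1
  y <- spec@signal
  nPar <- nComponents * 3 + 1 + (baseline == "linear")
  if (length(nu) < nPar + 1)
    stop("underdetermined fit: ", length(nu), " points for ", nPar,
         " parameters (two components need >= 8 points)")

  span <- diff(range(nu))
  starts <- seq(min(nu), max(nu), length.out = 5)
  g0 <- span / 4
  b0 <- min(y)
  a0 <- max(y) - b0

  best <- NULL
  for (c0 in starts) {
    start <- if (nComponents == 1) {
      list(A1 = a0, c1 = c0, g1 = g0, b = b0)
    } else {
      # second start center mirrored across the range midpoint
      list(A1 = a0, c1 = c0, g1 = g0,
           A2 = a0 / 2, c2 = min(nu) + max(nu) - c0, g2 = g0, b = b0)
    }
    form <- if (nComponents == 1) {
      y ~ A1 * g1^2 / ((nu - c1)^2 + g1^2) + b
    } else {
      y ~ A1 * g1^2 / ((nu - c1)^2 + g1^2) +
        A2 * g2^2 / ((nu - c2)^2 + g2^2) + b
    }
    if (baseline == "linear") {
      start$bs <- 0
      form <- stats::update(form, . ~ . + bs * (nu - mean(nu)))
    }
    # identifiability bounds: absorption bands are positive-going peaks; a
    # handful of samples cannot localize a center beyond the sampled window
    # (plus half a sampling step) nor support a band wider than the window
    step <- span / (length(nu) - 1)
    lowerOne <- c(0, min(nu) - step / 2, span / 20)
    upperOne <- c(Inf, max(nu) + step / 2, span)
    lower <- c(rep(lowerOne, nComponents), -Inf)
    upper <- c(rep(upperOne, nComponents), Inf)
    if (baseline == "linear") {
      lower <- c(lower, -Inf)
      upper <- c(upper, Inf)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(nu = nu, y = y),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # every start failed (e.g. a flat spectrum): report the degenerate
    # baseline-only solution with zero amplitude and an unreliable center
    return(data.frame(centerCm1 = NA_real_, hwhmCm1 = NA_real_,
                      amplitude = 0, baseline = mean(y), baselineSlope = 0,
                      rss = sum((y - mean(y))^2), seCenter = NA_real_,
                      converged = FALSE, centerReliable = FALSE))
  }

  co <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(co)), names(co)))
  dofRes <- max(length(nu) - length(co), 1)
  sigmaRes <- sqrt(best$rss / dofRes)

  one <- function(i) {
    A <- co[paste0("A", i)]; cc <- co[paste0("c", i)]
    g <- abs(co[paste0("g", i)])
    data.frame(
      centerCm1 = unname(cc), hwhmCm1 = unname(g), amplitude = unname(A),
      baseline = unname(co["b"]),
      baselineSlope = if ("bs" %in% names(co)) unname(co["bs"]) else 0,
      rss = best$rss,
      seCenter = unname(se[paste0("c", i)]),
      converged = TRUE,
      # amplitude must clear the residual noise for the center to mean much
      centerReliable = unname(abs(A) > 3 * sigmaRes &
                                abs(A) > 1e-6 * max(abs(y))))
  }
  out <- do.call(rbind, lapply(seq_len(nComponents), one))
  out[order(out$centerCm1), , drop = FALSE]
}

#' Isotope peak ratio between two co-registered FMIP volumes
#'
#' Ratio of ROI-mean FMIP intensity at the 13C-shifted carbonyl band
#' (1704 cm^-1) to the unshifted ester band (1744 cm^-1): the fraction of
#' lipid built from labeled fatty-acid uptake relative to de novo
#' synthesis. Also segments droplets on the denominator volume (Otsu
#' threshold, 6-connected components of at least `minVoxels` voxels) and
#' reports per-droplet ratios with box-plot summary statistics.
#'
#' Invariant to a common multiplicative gain on both volumes.
#'
#' @param vol1704 FMIP volume pumped at the shifted band.
#' @param vol1744 FMIP volume pumped at the unshifted band (denominator;
#'   also the segmentation channel).
#' @param roi optional logical array restricting the global ratio.
#' @param minVoxels minimum droplet size in voxels (default 4).
#' @return list with `ratio` (scalar), `perDroplet` (data.frame: droplet id,
#'   voxel count, ratio), and `summary` (mean, median, quartiles, range of
#'   per-droplet ratios).
#' @export
peakRatio <- function(vol1704, vol1744, roi = NULL, minVoxels = 4L) {
  a <- vol1704@data
  b <- vol1744@data
  if (!identical(dim(a), dim(b)))
    stop("volumes are not co-registered (dimension mismatch)")
  if (is.null(roi)) roi <- array(TRUE, dim(a)) else roi <- as.logical(roi)
  den <- mean(b[roi])
  if (den <= 0) stop("denominator ROI mean is not positive")
  ratio <- mean(a[roi]) / den

  thr <- otsuThreshold(b)
  labels <- labelComponents3d(b > thr)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  per <- do.call(rbind, lapply(ids, function(id) {
    vox <- labels == id
    if (sum(vox) < minVoxels) return(NULL)
    dmean <- mean(b[vox])
    data.frame(droplet = id, nVoxels = sum(vox),
               ratio = if (dmean > 0) mean(a[vox]) / dmean else NA_real_)
  }))
  if (is.null(per))
    per <- data.frame(droplet = integer(), nVoxels = integer(),
                      ratio = numeric())
  r <- per$ratio[is.finite(per$ratio)]
  summary <- if (length(r)) {
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    list(mean = mean(r), median = q[2], q25 = q[1], q75 = q[3],
         min = min(r), max = max(r), n = length(r))
  } else {
    list(mean = NA_real_, median = NA_real_, q25 = NA_real_,
         q75 = NA_real_, min = NA_real_, max = NA_real_, n = 0L)
  }
  list(ratio = ratio, perDroplet = per, summary = summary)
}
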