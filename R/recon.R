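## recon: regularized light-field deconvolution
##
##   minimize_x  1/2 ||Hx - y||^2 + lambda_l1 ||x||_1 + lambda_tv TV3D(x)
##               subject to x >= 0  (optional)
##
## solved by consensus ADMM with three splits: an l1 copy handled by
## soft-thresholding, a gradient-field copy handled by group (isotropic-TV)
## shrinkage, and a nonnegativity copy handled by projection. The quadratic
## x-update is solved in operator form by warm-started conjugate gradients
## on the normal equations — H is never materialized. The penalty rho is
## fixed (no adaptive scheme), which keeps every update positively
## homogeneous: scaling the measurement and the lambdas by c > 0 scales the
## whole iterate sequence, and hence the solution, by c.

# forward differences with replicate boundary (last difference zero)
gradOp <- function(x) {
  d <- dim(x)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) gy[-d[1], , ] <- x[-1, , , drop = FALSE] - x[-d[1], , , drop = FALSE]
  if (d[2] > 1) gx[, -d[2], ] <- x[, -1, , drop = FALSE] - x[, -d[2], , drop = FALSE]
  if (d[3] > 1) gz[, , -d[3]] <- x[, , -1, drop = FALSE] - x[, , -d[3], drop = FALSE]
  list(gy = gy, gx = gx, gz = gz)
}

# adjoint of gradOp (negative divergence)
gradAdj <- function(g) {
  d <- dim(g$gy)
  out <- array(0, d)
  if (d[1] > 1) {
    out[-1, , ] <- out[-1, , , drop = FALSE] + g$gy[-d[1], , , drop = FALSE]
    out[-d[1], , ] <- out[-d[1], , , drop = FALSE] - g$gy[-d[1], , , drop = FALSE]
  }
  if (d[2] > 1) {
    out[, -1, ] <- out[, -1, , drop = FALSE] + g$gx[, -d[2], , drop = FALSE]
    out[, -d[2], ] <- out[, -d[2], , drop = FALSE] - g$gx[, -d[2], , drop = FALSE]
  }
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1, drop = FALSE] + g$gz[, , -d[3], drop = FALSE]
    out[, , -d[3]] <- out[, , -d[3], drop = FALSE] - g$gz[, , -d[3], drop = FALSE]
  }
  out
}

#' Isotropic 3D total variation
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient
#' (replicate boundary: the last difference along each axis is zero; axes of
#' length one contribute nothing).
#'
#' @param volume a [Volume-class] or a 3D numeric array.
#' @return nonnegative scalar.
#' @examples
#' v <- array(0, c(2, 1, 1)); v[2, 1, 1] <- 1
#' tv3d(v)  # a single unit step: TV = 1
#' @export
tv3d <- function(volume) {
  x <- if (methods::is(volume, "Volume")) volume@data else volume
  g <- gradOp(x)
  sum(sqrt(g$gy^2 + g$gx^2 + g$gz^2))
}

groupShrink <- function(g, k) {
  mag <- sqrt(g$gy^2 + g$gx^2 + g$gz^2)
  scale <- ifelse(mag > 0, pmax(1 - k / mag, 0), 0)
  list(gy = g$gy * scale, gx = g$gx * scale, gz = g$gz * scale)
}

# CG on Q x = rhs, Q supplied as a function; warm start x0
cgSolve <- function(Q, rhs, x0, iters, tol = 1e-12) {
  x <- x0
  r <- rhs - Q(x)
  p <- r
  rs <- sum(r * r)
  rhsN <- sum(rhs * rhs)
  for (i in seq_len(iters)) {
    if (rs <= tol^2 * max(rhsN, 1e-300)) break
    Qp <- Q(p)
    alpha <- rs / sum(p * Qp)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Qp
    rsNew <- sum(r * r)
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  x
}

#' Axial full width at half maximum of a PSF stack
#'
#' Gaussian fit to the per-slice peak intensity versus depth; falls back to
#' the half-maximum crossing width if the fit fails. Also reports the
#' best-focus position.
#'
#' @param psf a [PSFStack-class].
#' @return list with `fwhmUm` and `bestFocusUm`.
#' @export
psfAxialFwhm <- function(psf) {
  prof <- apply(psf@data, 3, max)
  zs <- psf@zPositionsUm
  fit <- tryCatch(gaussianProfileFit(prof, zs), error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$fwhm) && fit$fwhm > 0) {
    return(list(fwhmUm = fit$fwhm, bestFocusUm = fit$center))
  }
  # half-max crossing fallback
  half <- min(prof) + (max(prof) - min(prof)) / 2
  above <- which(prof >= half)
  list(fwhmUm = diff(range(zs[above])) + diff(zs)[1],
       bestFocusUm = zs[which.max(prof)])
}

#' @describeIn reconstruct ADMM solution of the l1 + 3D-TV regularized
#'   least-squares deconvolution. With both weights zero and nonnegativity
#'   off, plain conjugate gradients on the normal equations are used
#'   instead. When `depthClipAxialFwhmMultiplier > 0`, slices farther than
#'   that multiple of the PSF's axial FWHM from its best-focus plane are
#'   zeroed post hoc (reconstruction content outside roughly twice the
#'   axial FWHM is unreliable and appears as edge artifacts).
#' @export
setMethod("reconstruct",
          signature("LightFieldFrame", "PSFStack", "ReconSettings"),
  function(frame, psf, settings) {
    y <- frame@data
    if (any(is.nan(y))) stop("NaN in measurement")
    dps <- dim(psf@data)
    ny <- nrow(y) - dps[1] + 1L
    nx <- ncol(y) - dps[2] + 1L
    if (ny < 1 || nx < 1)
      stop("frame canvas smaller than the PSF canvas: geometry mismatch")
    op <- psfOperator(psf, ny, nx)
    if (op$outV != nrow(y) || op$outU != ncol(y))
      stop("frame canvas does not match the projection geometry")
    nz <- op$nz
    dims <- c(ny, nx, nz)
    b <- applyAdjoint(y, op)

    l1 <- settings@lambdaL1
    tv <- settings@lambdaTv
    rho <- settings@admmRho
    useTv <- tv > 0
    useNn <- settings@nonnegativity

    objective <- function(x) {
      r <- applyForward(x, op) - y
      0.5 * sum(r^2) + l1 * sum(abs(x)) + (if (useTv) tv * tv3d(x) else 0)
    }

    objTrace <- numeric(0)
    priTrace <- numeric(0)
    duTrace <- numeric(0)
    converged <- FALSE

    if (l1 == 0 && !useTv && !useNn) {
      # unregularized least squares: straight CG on H'H x = H'y
      x <- array(0, dims)
      r <- b
      p <- r
      rs <- sum(r * r)
      iters <- 0L
      for (i in seq_len(settings@maxIters)) {
        Qp <- applyAdjoint(applyForward(p, op), op)
        alpha <- rs / sum(p * Qp)
        if (!is.finite(alpha)) break
        xNew <- x + alpha * p
        relChange <- relL2(xNew, x)
        x <- xNew
        r <- r - alpha * Qp
        rsNew <- sum(r * r)
        p <- r + (rsNew / rs) * p
        rs <- rsNew
        iters <- i
        objTrace <- c(objTrace, objective(x))
        priTrace <- c(priTrace, sqrt(rs))
        duTrace <- c(duTrace, sqrt(rs))
        if (relChange < settings@relTol) { converged <- TRUE; break }
      }
    } else {
      nIdSplits <- 1 + as.integer(useNn)  # l1 copy (+ nonneg copy)
      Q <- function(v) {
        out <- applyAdjoint(applyForward(v, op), op) + rho * nIdSplits * v
        if (useTv) out <- out + rho * gradAdj(gradOp(v))
        out
      }
      zero <- array(0, dims)
      x <- zero
      z1 <- zero; u1 <- zero
      z2 <- zero; u2 <- zero
      if (useTv) {
        w <- gradOp(zero); uw <- gradOp(zero)
      }
      iters <- 0L
      for (i in seq_len(settings@maxIters)) {
        rhs <- b + rho * (z1 - u1)
        if (useNn) rhs <- rhs + rho * (z2 - u2)
        if (useTv) rhs <- rhs + rho * gradAdj(list(
          gy = w$gy - uw$gy, gx = w$gx - uw$gx, gz = w$gz - uw$gz))
        xPrev <- x
        x <- cgSolve(Q, rhs, x, settings@cgIters)

        z1Old <- z1
        z1 <- softThreshold(x + u1, l1 / rho)
        u1 <- u1 + x - z1
        pri2 <- sum((x - z1)^2)
        du2 <- sum((z1 - z1Old)^2)
        if (useNn) {
          z2Old <- z2
          z2 <- pmax(x + u2, 0)
          u2 <- u2 + x - z2
          pri2 <- pri2 + sum((x - z2)^2)
          du2 <- du2 + sum((z2 - z2Old)^2)
        }
        if (useTv) {
          gx <- gradOp(x)
          wOld <- w
          w <- groupShrink(list(gy = gx$gy + uw$gy, gx = gx$gx + uw$gx,
                                gz = gx$gz + uw$gz), tv / rho)
          uw <- list(gy = uw$gy + gx$gy - w$gy,
                     gx = uw$gx + gx$gx - w$gx,
                     gz = uw$gz + gx$gz - w$gz)
          pri2 <- pri2 + sum((gx$gy - w$gy)^2) + sum((gx$gx - w$gx)^2) +
            sum((gx$gz - w$gz)^2)
          du2 <- du2 + sum((w$gy - wOld$gy)^2) + sum((w$gx - wOld$gx)^2) +
            sum((w$gz - wOld$gz)^2)
        }
        iters <- i
        xFeas <- if (useNn) pmax(x, 0) else x
        objTrace <- c(objTrace, objective(xFeas))
        priTrace <- c(priTrace, sqrt(pri2))
        duTrace <- c(duTrace, rho * sqrt(du2))
        if (relL2(x, xPrev) < settings@relTol) { converged <- TRUE; break }
      }
      if (useNn) x <- pmax(x, 0)
    }

    # post-hoc axial clipping around the PSF's best-focus plane
    if (settings@depthClipAxialFwhmMultiplier > 0 && nz > 1) {
      ax <- psfAxialFwhm(psf)
      keep <- abs(psf@zPositionsUm - ax$bestFocusUm) <=
        settings@depthClipAxialFwhmMultiplier * ax$fwhmUm
      x[, , !keep] <- 0
    }

    dz <- if (nz > 1) diff(psf@zPositionsUm)[1] else psf@pixelUm
    vol <- flfVolume(x, voxelSizeUm = c(psf@pixelUm, psf@pixelUm, dz),
                     zPositionsUm = psf@zPositionsUm,
                     signed = any(x < 0))
    new("ReconResult", volume = vol, objectiveTrace = objTrace,
        primalResiduals = priTrace, dualResiduals = duTrace,
        iterationsRun = iters, converged = converged)
  })
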