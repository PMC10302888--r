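## phantom: ground-truthed synthetic scenes.
##
## Emulates everything the instrument acquires: fluorophore-density volumes
## with per-band absorption maps, IR-on/IR-off frame pairs with photothermal
## modulation and camera noise, and single-bead calibration z-stacks.
## Photothermal physics: heating is local (the thermal diffusion length,
## ~165 nm for a 50 ns pulse in water, is sub-voxel at 0.3 um sampling), so
## the temperature field is taken proportional to the local absorption with
## no diffusion blur, and the fluorescence is modulated multiplicatively
## *before* projection — heating happens at the object, not on the camera.

# run expr with a local RNG state derived from seed
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

volumeGridFromConfig <- function(cfg) {
  list(ny = round(cfg@fovUm[2] / cfg@voxelSizeUm[2]),
       nx = round(cfg@fovUm[1] / cfg@voxelSizeUm[1]),
       zs = zGridUm(cfg@zRangeUm, cfg@voxelSizeUm[3]),
       vs = cfg@voxelSizeUm)
}

# physical position (um, lateral origin at volume center) -> voxel index
posToIndex <- function(p, grid) {
  c(iy = round(p[2] / grid$vs[2] + (grid$ny + 1) / 2),
    ix = round(p[1] / grid$vs[1] + (grid$nx + 1) / 2),
    iz = which.min(abs(grid$zs - p[3])))
}

#' Generate a ground-truthed phantom volume
#'
#' Builds the fluorophore-density volume for the requested scene plus one
#' absorption volume per vibrational band (amplitude-scaled indicator of
#' the object class that carries the band). Scenes: sub-voxel beads;
#' rod-shaped bacteria dried on a tilted substrate so depth spans the axial
#' range; a cell whose cytoplasm (nucleus excluded) holds spherical lipid
#' droplets, a fraction of which carry the 13C-shifted band.
#'
#' @param spec a [PhantomSpec-class].
#' @param cfg an [OpticalConfig-class] defining the voxel grid.
#' @return list: `fluorescence` ([Volume-class]), `absorption` (named list
#'   of [Volume-class], one per band class present in the scene),
#'   `positionsUm` (object centers: x, y, z in um, lateral origin at the
#'   volume center), `classes` (object class per row).
#' @export
generateVolume <- function(spec, cfg = opticalConfig()) {
  g <- volumeGridFromConfig(cfg)
  withSeed(spec@seed, switch(spec@kind,
    "beads" = phantomBeads(spec, g),
    "rods-on-tilted-substrate" = phantomRods(spec, g),
    "cell-with-droplets" = phantomCell(spec, g)))
}

geomPar <- function(spec, name, default) {
  v <- spec@geometry[[name]]
  if (is.null(v)) default else v
}

emptyScene <- function(g) {
  array(0, dim = c(g$ny, g$nx, length(g$zs)))
}

finishScene <- function(fluor, classMaps, spec, g, positionsUm, classes) {
  mk <- function(a, signed = FALSE)
    flfVolume(a, voxelSizeUm = g$vs, zPositionsUm = g$zs, signed = signed)
  absorption <- list()
  for (i in seq_len(nrow(spec@bands))) {
    cl <- spec@bands$class[i]
    if (!is.null(classMaps[[cl]]))
      absorption[[cl]] <- mk(spec@bands$amplitude[i] * classMaps[[cl]])
  }
  list(fluorescence = mk(fluor), absorption = absorption,
       positionsUm = positionsUm, classes = classes)
}

phantomBeads <- function(spec, g) {
  n <- geomPar(spec, "n", 5L)
  intensity <- geomPar(spec, "intensity", 1)
  classes <- rep(geomPar(spec, "classes", "none"), length.out = n)
  pos <- geomPar(spec, "positionsUm", NULL)
  if (is.null(pos)) {
    minSep <- geomPar(spec, "minSeparationUm", 2.1)
    lim <- c(0.3 * g$nx * g$vs[1], 0.3 * g$ny * g$vs[2])
    zlim <- 0.8 * range(g$zs)
    pos <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pos) < n && tries < 1000 * n) {
      tries <- tries + 1
      cand <- c(stats::runif(1, -lim[1], lim[1]),
                stats::runif(1, -lim[2], lim[2]),
                stats::runif(1, zlim[1], zlim[2]))
      if (nrow(pos) == 0 ||
          min(sqrt(colSums((t(pos) - cand)^2))) >= minSep)
        pos <- rbind(pos, cand)
    }
    if (nrow(pos) < n)
      stop("could not place ", n, " beads in the field of view")
  } else {
    pos <- rbind(pos)
    if (nrow(pos) != n) n <- nrow(pos)
    inField <- abs(pos[, 1]) <= g$nx * g$vs[1] / 2 &
      abs(pos[, 2]) <= g$ny * g$vs[2] / 2 &
      pos[, 3] >= min(g$zs) & pos[, 3] <= max(g$zs)
    if (!all(inField)) stop("bead positions fall outside the field of view")
  }
  fluor <- emptyScene(g)
  classMaps <- list()
  for (i in seq_len(n)) {
    ind <- posToIndex(pos[i, ], g)
    fluor[ind[1], ind[2], ind[3]] <- fluor[ind[1], ind[2], ind[3]] + intensity
    cl <- classes[i]
    if (cl != "none") {
      if (is.null(classMaps[[cl]])) classMaps[[cl]] <- emptyScene(g)
      classMaps[[cl]][ind[1], ind[2], ind[3]] <- 1
    }
  }
  finishScene(fluor, classMaps, spec, g, pos, classes)
}

phantomRods <- function(spec, g) {
  n <- geomPar(spec, "n", 8L)
  lenUm <- geomPar(spec, "lengthUm", 2)
  radUm <- geomPar(spec, "radiusUm", 0.4)
  tiltDeg <- geomPar(spec, "tiltDeg", 20)
  cls <- geomPar(spec, "class", "protein")
  xmax <- g$nx * g$vs[1] / 2
  ymax <- g$ny * g$vs[2] / 2
  slope <- tan(tiltDeg * pi / 180)
  # rod centers on the substrate plane z = slope * y, clamped to the range
  yHalf <- if (slope > 0)
    min(ymax - lenUm, 0.9 * max(abs(range(g$zs))) / slope) else ymax - lenUm
  cy <- stats::runif(n, -yHalf, yHalf)
  cx <- stats::runif(n, -(xmax - lenUm), xmax - lenUm)
  cz <- slope * cy
  theta <- stats::runif(n, 0, pi)  # in-plane orientation
  fluor <- emptyScene(g)
  xs <- (seq_len(g$nx) - (g$nx + 1) / 2) * g$vs[1]
  ys <- (seq_len(g$ny) - (g$ny + 1) / 2) * g$vs[2]
  for (i in seq_len(n)) {
    ax <- c(cos(theta[i]), sin(theta[i]), 0)
    for (iz in seq_along(g$zs)) {
      dz <- g$zs[iz] - cz[i]
      if (abs(dz) > radUm + g$vs[3]) next
      for (iy in seq_along(ys)) {
        dy <- ys[iy] - cy[i]
        if (abs(dy) > lenUm / 2 + radUm) next
        dxv <- xs - cx[i]
        # distance from voxel to the rod's axis segment
        t <- pmin(pmax(dxv * ax[1] + dy * ax[2], -lenUm / 2), lenUm / 2)
        dist2 <- (dxv - t * ax[1])^2 + (dy - t * ax[2])^2 + dz^2
        hit <- dist2 <= radUm^2
        fluor[iy, hit, iz] <- 1
      }
    }
  }
  classMaps <- list()
  classMaps[[cls]] <- (fluor > 0) * 1
  finishScene(fluor, classMaps, spec, g, cbind(cx, cy, cz), rep(cls, n))
}

phantomCell <- function(spec, g) {
  cellR <- geomPar(spec, "cellRadiusUm", 8)
  nucR <- geomPar(spec, "nucleusRadiusUm", 3)
  nDrop <- geomPar(spec, "nDroplets", 12L)
  dropR <- geomPar(spec, "dropletRadiusRangeUm", c(0.5, 1.0))
  labFrac <- geomPar(spec, "labeledFraction", 0.5)
  zHalf <- min(cellR, 0.9 * max(abs(range(g$zs))))
  xmax <- g$nx * g$vs[1] / 2
  if (cellR > xmax) stop("cell does not fit the field of view")

  centers <- matrix(NA_real_, 0, 3)
  radii <- numeric(0)
  tries <- 0
  while (nrow(centers) < nDrop && tries < 2000 * nDrop) {
    tries <- tries + 1
    r <- stats::runif(1, dropR[1], dropR[2])
    cand <- c(stats::runif(2, -cellR, cellR), stats::runif(1, -zHalf, zHalf))
    inCell <- sum((cand / c(cellR, cellR, zHalf))^2) <= (1 - r / cellR)^2
    outNuc <- sqrt(sum(cand^2)) >= nucR + r
    clear <- nrow(centers) == 0 ||
      all(sqrt(colSums((t(centers) - cand)^2)) >= radii + r)
    if (inCell && outNuc && clear) {
      centers <- rbind(centers, cand)
      radii <- c(radii, r)
    }
  }
  if (nrow(centers) < nDrop)
    stop("could not place ", nDrop, " droplets inside the cell")
  labeled <- seq_len(nDrop) %in%
    sample.int(nDrop, round(labFrac * nDrop))
  classes <- ifelse(labeled, "lipid13c", "lipid")

  fluor <- emptyScene(g)
  classMaps <- list(lipid = emptyScene(g), lipid13c = emptyScene(g))
  xs <- (seq_len(g$nx) - (g$nx + 1) / 2) * g$vs[1]
  ys <- (seq_len(g$ny) - (g$ny + 1) / 2) * g$vs[2]
  for (i in seq_len(nDrop)) {
    for (iz in seq_along(g$zs)) {
      dz <- g$zs[iz] - centers[i, 3]
      if (abs(dz) > radii[i]) next
      rho2 <- radii[i]^2 - dz^2
      d2 <- outer((ys - centers[i, 2])^2, (xs - centers[i, 1])^2, `+`)
      hit <- d2 <= rho2
      sl <- fluor[, , iz]; sl[hit] <- 1; fluor[, , iz] <- sl
      cm <- classMaps[[classes[i]]]
      sl <- cm[, , iz]; sl[hit] <- 1; classMaps[[classes[i]]][, , iz] <- sl
    }
  }
  finishScene(fluor, classMaps, spec, g, centers, classes)
}

#' Photothermal modulation field of a phantom at one pump wavenumber
#'
#' `m(r) = modulationPerKelvin * temperatureRiseK *
#'  sum_bands L_band(nu) * absorption_band(r)` where each band's Lorentzian
#' is normalized to 1 at its center.
#'
#' @param vols output of [generateVolume()].
#' @param wavenumberCm1 pump wavenumber.
#' @param spec the [PhantomSpec-class].
#' @return numeric array of fractional modulation per voxel.
#' @export
modulationField <- function(vols, wavenumberCm1, spec) {
  m <- array(0, dim = dim(vols$fluorescence@data))
  for (i in seq_len(nrow(spec@bands))) {
    cl <- spec@bands$class[i]
    ab <- vols$absorption[[cl]]
    if (is.null(ab)) next
    m <- m + lorentzianLine(wavenumberCm1, spec@bands$centerCm1[i],
                            spec@bands$hwhmCm1[i]) * ab@data
  }
  m <- spec@modulationPerKelvin * spec@temperatureRiseK * m
  if (max(m) > 1)
    stop("unphysical spec: modulation exceeds 100% (max ",
         signif(max(m), 3), ")")
  m
}

#' Generate one IR-on / IR-off frame pair from a phantom
#'
#' IR-off projects the fluorescence volume; IR-on projects the fluorescence
#' attenuated by the photothermal [modulationField()]. Both frames are then
#' scaled so the brightest IR-off pixel carries `photonBudget` expected
#' photons, Poisson shot noise is drawn independently per frame, Gaussian
#' read noise is added, and negative counts are clipped. A zero or infinite
#' photon budget gives noiseless frames.
#'
#' Noise is seeded from `spec@seed` plus the rounded wavenumber, so a sweep
#' gets independent noise per pair while the whole run stays reproducible.
#' Override `noiseSeed` to draw replicate acquisitions of the same scene
#' with independent noise.
#'
#' @param vols output of [generateVolume()].
#' @param psf the [PSFStack-class] to image through.
#' @param wavenumberCm1 pump wavenumber, cm^-1.
#' @param spec the [PhantomSpec-class] (modulation and noise parameters).
#' @param cfg optional [OpticalConfig-class] for elemental-layout metadata.
#' @param noiseSeed RNG seed for this pair's noise draw.
#' @return a [FramePair-class].
#' @export
generateFramePair <- function(vols, psf, wavenumberCm1, spec, cfg = NULL,
                              noiseSeed = spec@seed + round(wavenumberCm1)) {
  m <- modulationField(vols, wavenumberCm1, spec)
  fl <- vols$fluorescence
  onVol <- methods::initialize(fl, data = fl@data * (1 - m))
  layout <- if (!is.null(cfg))
    frameLayout(cfg, dim(psf@data)[1:2], dim(fl@data)[1], dim(fl@data)[2])
  else emptyLayout()
  off <- project(fl, psf, layout = layout, exposureTag = "ir_off")
  on <- project(onVol, psf, layout = layout, exposureTag = "ir_on")

  offD <- off@data
  onD <- on@data
  if (is.finite(spec@photonBudget) && spec@photonBudget > 0) {
    scale <- spec@photonBudget / max(offD)
    offD <- offD * scale
    onD <- onD * scale
    withSeed(noiseSeed, {
      offD[] <- stats::rpois(length(offD), offD) +
        stats::rnorm(length(offD), 0, spec@readNoiseSd)
      onD[] <- stats::rpois(length(onD), onD) +
        stats::rnorm(length(onD), 0, spec@readNoiseSd)
    })
    offD <- pmax(offD, 0)
    onD <- pmax(onD, 0)
  }
  framePair(
    irOn = lightFieldFrame(onD, layout, "ir_on"),
    irOff = lightFieldFrame(offD, layout, "ir_off"),
    wavenumberCm1 = wavenumberCm1)
}

#' Generate a single-bead PSF calibration z-stack
#'
#' Emulates the one-time system calibration: a z-scan of one sub-resolution
#' fluorescent bead (100 nm steps in the real procedure; here the PSF
#' stack's own z grid). The stack is the PSF scaled to the photon budget
#' with shot and read noise; noiseless (`photonBudget` 0 or Inf) it equals
#' the PSF up to one global scale factor.
#'
#' @param psf the ground-truth [PSFStack-class].
#' @param photonBudget expected photons at the brightest pixel of the stack.
#' @param readNoiseSd Gaussian read noise, photons RMS.
#' @param seed RNG seed.
#' @return numeric 3D array (v, u, z) in photon units.
#' @export
generateBeadCalibrationStack <- function(psf, photonBudget = 10000,
                                         readNoiseSd = 2, seed = 1L) {
  stack <- psf@data
  if (is.finite(photonBudget) && photonBudget > 0) {
    stack <- stack * (photonBudget / max(stack))
    withSeed(seed, {
      stack[] <- stats::rpois(length(stack), stack) +
        stats::rnorm(length(stack), 0, readNoiseSd)
    })
    stack <- pmax(stack, 0)
  } else {
    stack <- stack / max(stack)
  }
  stack
}
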