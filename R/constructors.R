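#' Create an optical configuration
#'
#' Defaults describe a high-NA Fourier light-field fluorescence microscope:
#' a 100x / 0.95 NA dry objective, a 2 x 2 lenslet array at the pupil
#' conjugate with occupancy ratio N = 2, a 150 mm Fourier lens, 520 nm
#' pulsed excitation with emission collected above 550 nm, and a
#' reconstruction grid of 0.3 x 0.3 x 0.35 um voxels spanning +/- 2.8 um
#' axially (a 5.6 um deep imaging volume).
#'
#' @param numericalAperture objective NA in (0, 1].
#' @param magnification total magnification.
#' @param excitationWavelengthNm,emissionWavelengthNm wavelengths in nm.
#' @param lensletGrid integer pair (rows, cols).
#' @param lensletOccupancyN lenslets across the pupil diameter (>= 1).
#' @param fourierLensFocalMm Fourier-lens focal length, mm.
#' @param cameraPixelUm camera pixel pitch, um.
#' @param voxelSizeUm reconstruction voxel (dx, dy, dz), um.
#' @param zRangeUm axial range (z_min, z_max), um.
#' @param fovUm lateral field of view (x, y), um.
#' @return an [OpticalConfig-class].
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(numericalAperture = 0.95,
                          magnification = 100,
                          excitationWavelengthNm = 520,
                          emissionWavelengthNm = 560,
                          lensletGrid = c(2L, 2L),
                          lensletOccupancyN = 2,
                          fourierLensFocalMm = 150,
                          cameraPixelUm = 6.5,
                          voxelSizeUm = c(0.3, 0.3, 0.35),
                          zRangeUm = c(-2.8, 2.8),
                          fovUm = c(19.2, 19.2)) {
  new("OpticalConfig",
      numericalAperture = numericalAperture,
      magnification = magnification,
      excitationWavelengthNm = excitationWavelengthNm,
      emissionWavelengthNm = emissionWavelengthNm,
      lensletGrid = as.integer(lensletGrid),
      lensletOccupancyN = lensletOccupancyN,
      fourierLensFocalMm = fourierLensFocalMm,
      cameraPixelUm = cameraPixelUm,
      voxelSizeUm = voxelSizeUm,
      zRangeUm = zRangeUm,
      fovUm = fovUm)
}

#' Create a PSF stack
#'
#' @param data nonnegative array (v, u, z).
#' @param zPositionsUm uniform, strictly increasing z grid, um.
#' @param pixelUm lateral sample pitch, um.
#' @param normalization `"per-slice-sum-one"` or `"global-peak-one"`.
#' @param beadCentroids optional per-slice centroid matrix.
#' @return a [PSFStack-class].
#' @export
psfStack <- function(data, zPositionsUm, pixelUm,
                     normalization = "per-slice-sum-one",
                     beadCentroids = matrix(numeric(), 0, 2)) {
  new("PSFStack", data = data, zPositionsUm = zPositionsUm,
      pixelUm = pixelUm, normalization = normalization,
      beadCentroids = beadCentroids)
}

#' Create a volume
#'
#' @param data numeric array (y, x, z).
#' @param voxelSizeUm (dx, dy, dz), um.
#' @param zPositionsUm axial slice positions, um.
#' @param signed allow negative voxels (photothermal difference volumes).
#' @return a [Volume-class].
#' @export
flfVolume <- function(data, voxelSizeUm, zPositionsUm, signed = FALSE) {
  new("Volume", data = data, voxelSizeUm = voxelSizeUm,
      zPositionsUm = zPositionsUm, signed = signed)
}

#' Create a light-field frame
#'
#' @param data numeric matrix (v, u).
#' @param elementalLayout per-lenslet bounding boxes (see
#'   [LightFieldFrame-class]); an empty data.frame when unknown.
#' @param exposureTag `"ir_on"`, `"ir_off"`, `"plain"` or `"diff"`.
#' @return a [LightFieldFrame-class].
#' @export
lightFieldFrame <- function(data,
                            elementalLayout = emptyLayout(),
                            exposureTag = "plain") {
  new("LightFieldFrame", data = data, elementalLayout = elementalLayout,
      exposureTag = exposureTag)
}

emptyLayout <- function() {
  data.frame(row = integer(), col = integer(),
             v0 = integer(), v1 = integer(),
             u0 = integer(), u1 = integer())
}

#' Create a frame pair
#'
#' @param irOn,irOff the two [LightFieldFrame-class] exposures.
#' @param wavenumberCm1 pump wavenumber, cm^-1.
#' @return a [FramePair-class].
#' @export
framePair <- function(irOn, irOff, wavenumberCm1) {
  new("FramePair", irOn = irOn, irOff = irOff,
      wavenumberCm1 = wavenumberCm1)
}

#' Create reconstruction settings
#'
#' Defaults were tuned on the single-bead phantom: mild l1 and TV weights
#' relative to a measurement normalized to unit peak, a unit penalty
#' parameter, and enough iterations for the bead problem to converge.
#' Weights are absolute, so rescale them with the data (see the scaling
#' equivariance property of [reconstruct()]).
#'
#' @param lambdaL1 l1 weight (default 1e-3).
#' @param lambdaTv isotropic 3D TV weight (default 2e-4).
#' @param admmRho ADMM penalty parameter (default 1).
#' @param maxIters maximum ADMM iterations (default 60).
#' @param relTol stop when the relative iterate change falls below this
#'   (default 1e-6).
#' @param nonnegativity project onto x >= 0 (default TRUE; fluorophore
#'   density is physically nonnegative).
#' @param depthClipAxialFwhmMultiplier zero slices beyond this multiple of
#'   the PSF axial FWHM from best focus (default 2; 0 disables).
#' @param cgIters conjugate-gradient iterations per quadratic subproblem
#'   (default 8).
#' @return a [ReconSettings-class].
#' @export
reconSettings <- function(lambdaL1 = 1e-3,
                          lambdaTv = 2e-4,
                          admmRho = 1,
                          maxIters = 60L,
                          relTol = 1e-6,
                          nonnegativity = TRUE,
                          depthClipAxialFwhmMultiplier = 2,
                          cgIters = 8L) {
  new("ReconSettings", lambdaL1 = lambdaL1, lambdaTv = lambdaTv,
      admmRho = admmRho, maxIters = as.integer(maxIters), relTol = relTol,
      nonnegativity = nonnegativity,
      depthClipAxialFwhmMultiplier = depthClipAxialFwhmMultiplier,
      cgIters = as.integer(cgIters))
}

#' Create an FMIP spectrum
#'
#' @param wavenumbersCm1 strictly increasing wavenumbers, cm^-1.
#' @param signal FMIP signal per wavenumber.
#' @param signalSd per-point SD across replicates (NA if single replicate).
#' @param nReplicates replicate count.
#' @return an [FMIPSpectrum-class].
#' @export
fmipSpectrum <- function(wavenumbersCm1, signal,
                         signalSd = rep(NA_real_, length(signal)),
                         nReplicates = 1L) {
  new("FMIPSpectrum", wavenumbersCm1 = wavenumbersCm1, signal = signal,
      signalSd = signalSd, nReplicates = as.integer(nReplicates))
}

#' Default vibrational absorption bands for phantom object classes
#'
#' Three Lorentzian bands: the endogenous esterified-lipid C=O stretch at
#' 1744 cm^-1, its 13C-shifted counterpart at 1704 cm^-1 (lipids built from
#' isotopically labeled fatty acids), and the protein amide-I band at
#' 1650 cm^-1.
#'
#' @return data.frame with columns class, centerCm1, hwhmCm1, amplitude.
#' @export
defaultBands <- function() {
  data.frame(
    class = c("lipid", "lipid13c", "protein"),
    centerCm1 = c(1744, 1704, 1650),
    hwhmCm1 = c(10, 10, 15),
    amplitude = c(1, 1, 1)
  )
}

#' Create a phantom specification
#'
#' @param kind `"beads"`, `"rods-on-tilted-substrate"` or
#'   `"cell-with-droplets"`.
#' @param geometry named list; recognized entries by kind:
#'   * beads: `n` (count), `positionsUm` (optional n x 3 matrix, x/y/z um),
#'     `classes` (per-bead band class or `"none"`), `intensity`.
#'   * rods-on-tilted-substrate: `n`, `lengthUm`, `radiusUm`,
#'     `tiltDeg` (substrate tilt; 0 puts all rods in one plane), `class`.
#'   * cell-with-droplets: `cellRadiusUm`, `nucleusRadiusUm` (droplets are
#'     excluded from the nucleus), `nDroplets`, `dropletRadiusRangeUm`,
#'     `labeledFraction` (fraction of droplets carrying the 13C band).
#' @param bands absorption bands per class; see [defaultBands()].
#' @param modulationPerKelvin fractional fluorescence loss per Kelvin
#'   (default 0.01).
#' @param temperatureRiseK peak photothermal temperature rise (default 1 K).
#' @param photonBudget expected photons at the brightest pixel
#'   (default 10000; 0 or Inf for noiseless frames).
#' @param readNoiseSd Gaussian read noise, photons RMS (default 2).
#' @param seed RNG seed (default 1).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(kind = "beads",
                        geometry = list(),
                        bands = defaultBands(),
                        modulationPerKelvin = 0.01,
                        temperatureRiseK = 1,
                        photonBudget = 10000,
                        readNoiseSd = 2,
                        seed = 1L) {
  new("PhantomSpec", kind = kind, geometry = geometry, bands = bands,
      modulationPerKelvin = modulationPerKelvin,
      temperatureRiseK = temperatureRiseK,
      photonBudget = photonBudget, readNoiseSd = readNoiseSd,
      seed = as.integer(seed))
}
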