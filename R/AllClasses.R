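#' @import methods
NULL

## Axis conventions used throughout:
##  - volumes are arrays indexed [y, x, z]; camera frames are matrices [v, u]
##  - pixel/voxel indices are 1-based (R), physical coordinates in micrometers
##  - z = 0 is the nominal focal plane, positive toward the objective

#' Optical configuration of an FLF instrument
#'
#' Holds every instrument parameter the simulation and reconstruction need:
#' objective aperture and magnification, excitation/emission wavelengths,
#' lenslet-array layout, Fourier-lens focal length, camera pixel pitch, the
#' reconstruction voxel grid, the axial range, and the lateral field of view.
#'
#' @slot numericalAperture objective NA, dimensionless in (0, 1].
#' @slot magnification total magnification, dimensionless, > 0.
#' @slot excitationWavelengthNm excitation wavelength in nanometers.
#' @slot emissionWavelengthNm emission wavelength in nanometers (must be
#'   at least the excitation wavelength).
#' @slot lensletGrid integer pair (rows, cols) of the lenslet array.
#' @slot lensletOccupancyN number of lenslets spanning the pupil diameter
#'   (occupancy ratio N), dimensionless, >= 1.
#' @slot fourierLensFocalMm Fourier-lens focal length in millimeters.
#' @slot cameraPixelUm physical camera pixel pitch in micrometers.
#' @slot voxelSizeUm numeric triple (dx, dy, dz) in micrometers.
#' @slot zRangeUm numeric pair (z_min, z_max) in micrometers.
#' @slot fovUm numeric pair, lateral field of view (x, y) in micrometers.
#'
#' @seealso [opticalConfig()]
#' @export
setClass("OpticalConfig",
  representation(
    numericalAperture = "numeric",
    magnification = "numeric",
    excitationWavelengthNm = "numeric",
    emissionWavelengthNm = "numeric",
    lensletGrid = "integer",
    lensletOccupancyN = "numeric",
    fourierLensFocalMm = "numeric",
    cameraPixelUm = "numeric",
    voxelSizeUm = "numeric",
    zRangeUm = "numeric",
    fovUm = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@numericalAperture) != 1 ||
      object@numericalAperture <= 0 || object@numericalAperture > 1)
    msg <- c(msg, "numericalAperture must be a scalar in (0, 1]")
  if (object@magnification <= 0)
    msg <- c(msg, "magnification must be > 0")
  pos <- c(object@excitationWavelengthNm, object@emissionWavelengthNm,
           object@fourierLensFocalMm, object@cameraPixelUm,
           object@voxelSizeUm, object@fovUm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all lengths must be finite and strictly positive")
  if (object@emissionWavelengthNm < object@excitationWavelengthNm)
    msg <- c(msg, "emission wavelength must be >= excitation wavelength")
  if (length(object@lensletGrid) != 2 || any(object@lensletGrid < 1L))
    msg <- c(msg, "lensletGrid must be two integers >= 1")
  if (object@lensletOccupancyN < 1)
    msg <- c(msg, "lensletOccupancyN must be >= 1")
  if (length(object@voxelSizeUm) != 3)
    msg <- c(msg, "voxelSizeUm must be (dx, dy, dz)")
  if (length(object@zRangeUm) != 2 || object@zRangeUm[1] >= object@zRangeUm[2])
    msg <- c(msg, "zRangeUm must satisfy z_min < z_max")
  if (length(msg)) msg else TRUE
})

#' Z-indexed stack of 2D light-field point spread functions
#'
#' The calibrated (or simulated) depth-dependent PSF of the instrument: one
#' nonnegative 2D light-field image per axial position, all on a common
#' camera canvas. This stack is the convolution kernel of the image-formation
#' model used by [project()] and [reconstruct()].
#'
#' @slot data nonnegative numeric array of dimension (v, u, z).
#' @slot zPositionsUm strictly increasing, uniformly spaced axial positions
#'   in micrometers.
#' @slot pixelUm lateral sample pitch of the canvas in micrometers (object
#'   space; matches the volume's lateral voxel pitch).
#' @slot normalization one of `"per-slice-sum-one"` (each depth slice sums to
#'   1, so the forward model conserves per-slice flux) or
#'   `"global-peak-one"`.
#' @slot beadCentroids optional per-slice bead centroid (row, col) recorded
#'   by [calibratePsfFromBeads()]; zero-row matrix when not applicable.
#'
#' @seealso [simulatePsfStack()], [calibratePsfFromBeads()]
#' @export
setClass("PSFStack",
  representation(
    data = "array",
    zPositionsUm = "numeric",
    pixelUm = "numeric",
    normalization = "character",
    beadCentroids = "matrix"
  )
)

setValidity("PSFStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3D array (v, u, z)")
  else if (dim(object@data)[3] != length(object@zPositionsUm))
    msg <- c(msg, "number of z slices must equal length(zPositionsUm)")
  if (any(object@data < 0))
    msg <- c(msg, "PSF values must be nonnegative")
  nz <- length(object@zPositionsUm)
  if (nz >= 2) {
    dz <- diff(object@zPositionsUm)
    if (any(dz <= 0))
      msg <- c(msg, "zPositionsUm must be strictly increasing")
    else if (max(abs(dz - dz[1])) > 1e-6 * abs(dz[1]))
      msg <- c(msg, "z spacing must be uniform (1e-6 relative tolerance)")
  }
  if (!object@normalization %in% c("per-slice-sum-one", "global-peak-one"))
    msg <- c(msg, "unknown normalization")
  if (length(object@pixelUm) != 1 || object@pixelUm <= 0)
    msg <- c(msg, "pixelUm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' A 3D fluorophore-density volume on a voxel grid
#'
#' The object being imaged (or reconstructed): a nonnegative density per
#' voxel. FMIP difference volumes relax nonnegativity (photothermal signal
#' volumes may carry either sign), controlled by the `signed` flag.
#'
#' @slot data numeric array of dimension (y, x, z).
#' @slot voxelSizeUm numeric triple (dx, dy, dz) in micrometers.
#' @slot zPositionsUm axial position of each slice, micrometers.
#' @slot signed logical; FALSE (default) enforces nonnegativity.
#'
#' @export
setClass("Volume",
  representation(
    data = "array",
    voxelSizeUm = "numeric",
    zPositionsUm = "numeric",
    signed = "logical"
  )
)

setValidity("Volume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3D array (y, x, z)")
  else if (dim(object@data)[3] != length(object@zPositionsUm))
    msg <- c(msg, "z axis length must equal length(zPositionsUm)")
  if (!object@signed && any(object@data < 0))
    msg <- c(msg, "volume values must be nonnegative")
  if (length(object@voxelSizeUm) != 3 || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be three positive values")
  if (length(msg)) msg else TRUE
})

#' One 2D light-field camera frame
#'
#' A single sensor measurement: the composite canvas carrying all elemental
#' (per-lenslet perspective) images, plus the bounding box of each elemental
#' image and an exposure tag recording whether the mid-IR pump was on.
#' Plain fluorescence frames are nonnegative; difference frames produced by
#' [fmipDifference()] carry tag `"diff"` and may hold negative pixels.
#'
#' @slot data numeric matrix (v, u).
#' @slot elementalLayout data.frame with one row per lenslet: columns
#'   `row`, `col` (lenslet index), `v0`, `v1`, `u0`, `u1` (inclusive 1-based
#'   bounding box on the canvas). Boxes are pairwise disjoint.
#' @slot exposureTag one of `"ir_on"`, `"ir_off"`, `"plain"`, `"diff"`.
#'
#' @export
setClass("LightFieldFrame",
  representation(
    data = "matrix",
    elementalLayout = "data.frame",
    exposureTag = "character"
  )
)

setValidity("LightFieldFrame", function(object) {
  msg <- character()
  if (!object@exposureTag %in% c("ir_on", "ir_off", "plain", "diff"))
    msg <- c(msg, "exposureTag must be ir_on, ir_off, plain or diff")
  if (object@exposureTag != "diff" && any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "frame values must be nonnegative")
  lay <- object@elementalLayout
  if (nrow(lay) > 1) {
    # elemental images must not overlap on the canvas
    for (i in seq_len(nrow(lay) - 1)) {
      for (j in seq(i + 1, nrow(lay))) {
        if (lay$v0[i] <= lay$v1[j] && lay$v0[j] <= lay$v1[i] &&
            lay$u0[i] <= lay$u1[j] && lay$u0[j] <= lay$u1[i]) {
          msg <- c(msg, "elemental bounding boxes must be disjoint")
          break
        }
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Paired IR-on / IR-off light-field frames at one pump wavenumber
#'
#' @slot irOn,irOff [LightFieldFrame-class] objects sharing canvas geometry.
#' @slot wavenumberCm1 mid-IR pump wavenumber for this pair (cm^-1).
#'
#' @export
setClass("FramePair",
  representation(
    irOn = "LightFieldFrame",
    irOff = "LightFieldFrame",
    wavenumberCm1 = "numeric"
  )
)

setValidity("FramePair", function(object) {
  msg <- character()
  if (!identical(dim(object@irOn@data), dim(object@irOff@data)))
    msg <- c(msg, "irOn and irOff must share canvas geometry")
  if (object@irOn@exposureTag != "ir_on" ||
      object@irOff@exposureTag != "ir_off")
    msg <- c(msg, "exposure tags must be ir_on / ir_off")
  if (length(object@wavenumberCm1) != 1 || object@wavenumberCm1 <= 0)
    msg <- c(msg, "wavenumberCm1 must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Settings for the ADMM deconvolution solver
#'
#' @slot lambdaL1 nonnegative l1 (sparsity) weight.
#' @slot lambdaTv nonnegative isotropic 3D total-variation weight.
#' @slot admmRho positive ADMM penalty parameter.
#' @slot maxIters maximum number of ADMM iterations (>= 1).
#' @slot relTol convergence tolerance on the relative change of the iterate.
#' @slot nonnegativity enforce x >= 0 through a projection split.
#' @slot depthClipAxialFwhmMultiplier after solving, zero slices farther than
#'   this multiple of the PSF's axial FWHM from its best-focus plane
#'   (0 disables; default 2).
#' @slot cgIters conjugate-gradient iterations for the quadratic subproblem.
#'
#' @seealso [reconSettings()], [reconstruct()]
#' @export
setClass("ReconSettings",
  representation(
    lambdaL1 = "numeric",
    lambdaTv = "numeric",
    admmRho = "numeric",
    maxIters = "integer",
    relTol = "numeric",
    nonnegativity = "logical",
    depthClipAxialFwhmMultiplier = "numeric",
    cgIters = "integer"
  )
)

setValidity("ReconSettings", function(object) {
  msg <- character()
  if (object@lambdaL1 < 0 || object@lambdaTv < 0)
    msg <- c(msg, "regularization weights must be nonnegative")
  if (object@admmRho <= 0) msg <- c(msg, "admmRho must be positive")
  if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
  if (object@relTol <= 0) msg <- c(msg, "relTol must be positive")
  if (object@depthClipAxialFwhmMultiplier < 0)
    msg <- c(msg, "depthClipAxialFwhmMultiplier must be >= 0")
  if (object@cgIters < 1L) msg <- c(msg, "cgIters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of an ADMM reconstruction
#'
#' @slot volume the reconstructed [Volume-class].
#' @slot objectiveTrace merged objective (data fidelity + l1 + TV) per
#'   iteration.
#' @slot primalResiduals,dualResiduals per-iteration ADMM residual norms.
#' @slot iterationsRun number of iterations actually performed.
#' @slot converged TRUE if the relative-change stopping rule fired before
#'   `maxIters`.
#'
#' @export
setClass("ReconResult",
  representation(
    volume = "Volume",
    objectiveTrace = "numeric",
    primalResiduals = "numeric",
    dualResiduals = "numeric",
    iterationsRun = "integer",
    converged = "logical"
  )
)

setValidity("ReconResult", function(object) {
  msg <- character()
  if (length(object@objectiveTrace) != object@iterationsRun)
    msg <- c(msg, "objectiveTrace length must equal iterationsRun")
  if (length(msg)) msg else TRUE
})

#' An FMIP spectrum: photothermal signal versus pump wavenumber
#'
#' @slot wavenumbersCm1 strictly increasing pump wavenumbers (cm^-1),
#'   within the pump laser's 1175-1800 cm^-1 tuning range.
#' @slot signal dimensionless FMIP signal at each wavenumber.
#' @slot signalSd per-point standard deviation across replicates (NA when
#'   a single replicate was supplied).
#' @slot nReplicates number of replicates behind each point.
#'
#' @seealso [extractSpectrum()], [fitLorentzian()]
#' @export
setClass("FMIPSpectrum",
  representation(
    wavenumbersCm1 = "numeric",
    signal = "numeric",
    signalSd = "numeric",
    nReplicates = "integer"
  )
)

setValidity("FMIPSpectrum", function(object) {
  msg <- character()
  n <- length(object@wavenumbersCm1)
  if (length(object@signal) != n || length(object@signalSd) != n)
    msg <- c(msg, "wavenumbers, signal and signalSd must have equal length")
  if (n >= 2 && any(diff(object@wavenumbersCm1) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (any(object@wavenumbersCm1 < 1175) || any(object@wavenumbersCm1 > 1800))
    msg <- c(msg, "wavenumbers must lie within the 1175-1800 cm^-1 range")
  if (length(msg)) msg else TRUE
})

#' Synthetic-scene specification for the phantom generator
#'
#' Describes a ground-truthed synthetic scene: object geometry, the
#' vibrational bands (Lorentzian line shapes) each object class absorbs at,
#' the photothermal modulation physics, and the camera noise model. All
#' randomness flows from the single `seed`.
#'
#' @slot kind `"beads"`, `"rods-on-tilted-substrate"` or
#'   `"cell-with-droplets"`.
#' @slot geometry named list of geometry parameters; see [phantomSpec()].
#' @slot bands data.frame with columns `class`, `centerCm1`, `hwhmCm1`,
#'   `amplitude`: the Lorentzian absorption bands per object class.
#' @slot modulationPerKelvin fractional fluorescence modulation per Kelvin
#'   of photothermal heating (default 0.01: thermosensitive dyes lose about
#'   1% brightness per Kelvin).
#' @slot temperatureRiseK peak temperature rise of the scene, Kelvin.
#' @slot photonBudget expected photon count at the brightest IR-off pixel
#'   (Poisson shot noise); 0 or Inf disables shot noise.
#' @slot readNoiseSd additive Gaussian read noise (photons RMS).
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#'
#' @seealso [phantomSpec()], [generateVolume()], [generateFramePair()]
#' @export
setClass("PhantomSpec",
  representation(
    kind = "character",
    geometry = "list",
    bands = "data.frame",
    modulationPerKelvin = "numeric",
    temperatureRiseK = "numeric",
    photonBudget = "numeric",
    readNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@kind %in%
      c("beads", "rods-on-tilted-substrate", "cell-with-droplets"))
    msg <- c(msg, "unknown phantom kind")
  b <- object@bands
  need <- c("class", "centerCm1", "hwhmCm1", "amplitude")
  if (!all(need %in% names(b)))
    msg <- c(msg, "bands must have columns class, centerCm1, hwhmCm1, amplitude")
  else {
    if (any(b$hwhmCm1 <= 0)) msg <- c(msg, "band HWHM must be positive")
    if (any(b$amplitude < 0)) msg <- c(msg, "band amplitudes must be >= 0")
  }
  if (object@modulationPerKelvin < 0)
    msg <- c(msg, "modulationPerKelvin must be >= 0")
  if (object@temperatureRiseK < 0)
    msg <- c(msg, "temperatureRiseK must be >= 0")
  if (object@photonBudget < 0) msg <- c(msg, "photonBudget must be >= 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
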