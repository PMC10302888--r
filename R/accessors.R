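#' Accessors for flfmip data classes
#'
#' Slot accessors: `imageData` returns the pixel/voxel array of a
#' [PSFStack-class], [Volume-class] or [LightFieldFrame-class];
#' `zPositionsUm`, `voxelSizeUm`, `pixelUm`, `normalizationMode`,
#' `exposureTag`, `elementalLayout`, `wavenumbersCm1`, `spectrumSignal`
#' and `spectrumSd` return the corresponding metadata.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("imageData", "PSFStack", function(x) x@data)
#' @rdname accessors
setMethod("imageData", "Volume", function(x) x@data)
#' @rdname accessors
setMethod("imageData", "LightFieldFrame", function(x) x@data)

#' @rdname accessors
setMethod("zPositionsUm", "PSFStack", function(x) x@zPositionsUm)
#' @rdname accessors
setMethod("zPositionsUm", "Volume", function(x) x@zPositionsUm)

#' @rdname accessors
setMethod("voxelSizeUm", "Volume", function(x) x@voxelSizeUm)
#' @rdname accessors
setMethod("pixelUm", "PSFStack", function(x) x@pixelUm)
#' @rdname accessors
setMethod("normalizationMode", "PSFStack", function(x) x@normalization)

#' @rdname accessors
setMethod("exposureTag", "LightFieldFrame", function(x) x@exposureTag)
#' @rdname accessors
setMethod("elementalLayout", "LightFieldFrame", function(x) x@elementalLayout)

#' @rdname accessors
setMethod("wavenumbersCm1", "FMIPSpectrum", function(x) x@wavenumbersCm1)
#' @rdname accessors
setMethod("spectrumSignal", "FMIPSpectrum", function(x) x@signal)
#' @rdname accessors
setMethod("spectrumSd", "FMIPSpectrum", function(x) x@signalSd)

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig:",
      sprintf("%gx / %.2f NA,", object@magnification,
              object@numericalAperture),
      sprintf("%d x %d lenslets (N = %g)\n", object@lensletGrid[1],
              object@lensletGrid[2], object@lensletOccupancyN))
  cat(sprintf("  exc/em %g/%g nm; f_FL %g mm; camera pixel %g um\n",
              object@excitationWavelengthNm, object@emissionWavelengthNm,
              object@fourierLensFocalMm, object@cameraPixelUm))
  cat(sprintf("  voxel %g x %g x %g um; z range [%g, %g] um; FOV %g x %g um\n",
              object@voxelSizeUm[1], object@voxelSizeUm[2],
              object@voxelSizeUm[3], object@zRangeUm[1], object@zRangeUm[2],
              object@fovUm[1], object@fovUm[2]))
})

setMethod("show", "PSFStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("PSFStack: %d x %d canvas, %d depths [%g, %g] um (%s)\n",
              d[1], d[2], d[3], min(object@zPositionsUm),
              max(object@zPositionsUm), object@normalization))
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume: %d x %d x %d voxels (%g x %g x %g um)%s\n",
              d[1], d[2], d[3], object@voxelSizeUm[1], object@voxelSizeUm[2],
              object@voxelSizeUm[3], if (object@signed) ", signed" else ""))
})

setMethod("show", "LightFieldFrame", function(object) {
  cat(sprintf("LightFieldFrame: %d x %d px, tag '%s', %d elemental images\n",
              nrow(object@data), ncol(object@data), object@exposureTag,
              nrow(object@elementalLayout)))
})

setMethod("show", "FramePair", function(object) {
  cat(sprintf("FramePair at %g cm^-1: %d x %d px IR-on/IR-off\n",
              object@wavenumberCm1, nrow(object@irOn@data),
              ncol(object@irOn@data)))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d iterations, %sconverged, objective %.6g\n",
              object@iterationsRun, if (object@converged) "" else "NOT ",
              utils::tail(object@objectiveTrace, 1)))
})

setMethod("show", "FMIPSpectrum", function(object) {
  cat(sprintf("FMIPSpectrum: %d wavenumbers [%g, %g] cm^-1, N = %d\n",
              length(object@wavenumbersCm1), min(object@wavenumbersCm1),
              max(object@wavenumbersCm1), object@nReplicates))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d bands, %g%%/K modulation, dT = %g K, seed %d\n",
              object@kind, nrow(object@bands),
              100 * object@modulationPerKelvin, object@temperatureRiseK,
              object@seed))
})
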