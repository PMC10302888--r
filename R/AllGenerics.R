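#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("zPositionsUm", function(x) standardGeneric("zPositionsUm"))

#' @rdname accessors
#' @export
setGeneric("voxelSizeUm", function(x) standardGeneric("voxelSizeUm"))

#' @rdname accessors
#' @export
setGeneric("pixelUm", function(x) standardGeneric("pixelUm"))

#' @rdname accessors
#' @export
setGeneric("normalizationMode", function(x) standardGeneric("normalizationMode"))

#' @rdname accessors
#' @export
setGeneric("exposureTag", function(x) standardGeneric("exposureTag"))

#' @rdname accessors
#' @export
setGeneric("elementalLayout", function(x) standardGeneric("elementalLayout"))

#' @rdname accessors
#' @export
setGeneric("wavenumbersCm1", function(x) standardGeneric("wavenumbersCm1"))

#' @rdname accessors
#' @export
setGeneric("spectrumSignal", function(x) standardGeneric("spectrumSignal"))

#' @rdname accessors
#' @export
setGeneric("spectrumSd", function(x) standardGeneric("spectrumSd"))

#' Forward light-field projection of a volume
#'
#' @param volume a [Volume-class].
#' @param psf a [PSFStack-class] sharing the volume's z grid.
#' @param ... further arguments passed to methods.
#' @return a [LightFieldFrame-class].
#' @export
setGeneric("project", function(volume, psf, ...) standardGeneric("project"))

#' Adjoint (transpose) of the light-field projection
#'
#' @param frame a [LightFieldFrame-class].
#' @param psf a [PSFStack-class].
#' @param ... further arguments passed to methods.
#' @return a [Volume-class] (signed).
#' @export
setGeneric("adjointProject",
           function(frame, psf, ...) standardGeneric("adjointProject"))

#' Regularized light-field deconvolution
#'
#' @param frame a [LightFieldFrame-class] measurement.
#' @param psf the calibrated [PSFStack-class].
#' @param settings a [ReconSettings-class].
#' @param ... further arguments passed to methods.
#' @return a [ReconResult-class].
#' @export
setGeneric("reconstruct",
           function(frame, psf, settings, ...) standardGeneric("reconstruct"))
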