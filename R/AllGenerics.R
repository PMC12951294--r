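#' @rdname PressureImage-class
#' @param object,x a \linkS4class{PressureImage}
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname PressureImage-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname RingGeometry-class
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @rdname RingGeometry-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname RingGeometry-class
#' @export
setGeneric("speedOfSound", function(x) standardGeneric("speedOfSound"))

#' @rdname Sinogram-class
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname Sinogram-class
#' @export
setGeneric("detectorMask", function(x) standardGeneric("detectorMask"))

#' @rdname Sinogram-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname DiffusionSchedule-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname DiffusionSchedule-class
#' @export
setGeneric("noiseLevel", function(x) standardGeneric("noiseLevel"))
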