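#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname reflectance
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname specimenData
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' @rdname applyCentering
#' @export
setGeneric("applyCentering", function(model, x) standardGeneric("applyCentering"))

#' @rdname predictValues
#' @export
setGeneric("predictValues", function(object, x) standardGeneric("predictValues"))
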