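#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param object,x an object.
#' @param ... further arguments for methods.
#' @return The slot value (or derived value) documented in each method.
#' @name dwiQA-generics
#' @keywords internal
NULL

#' @rdname dwiQA-generics
#' @export
setGeneric("vials", function(object) standardGeneric("vials"))

#' @rdname dwiQA-generics
#' @export
setGeneric("nVials", function(object) standardGeneric("nVials"))

#' @rdname dwiQA-generics
#' @export
setGeneric("referenceAdc", function(object, vialId) standardGeneric("referenceAdc"))

#' @rdname dwiQA-generics
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname dwiQA-generics
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname dwiQA-generics
#' @export
setGeneric("decodeSignal", function(object) standardGeneric("decodeSignal"))

#' @rdname dwiQA-generics
#' @export
setGeneric("adcValues", function(object) standardGeneric("adcValues"))

#' @rdname dwiQA-generics
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname dwiQA-generics
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname dwiQA-generics
#' @export
setGeneric("adcUnits", function(object) standardGeneric("adcUnits"))
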