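#' @rdname TPEFField-class
#' @param object,x a package object
#' @export
setGeneric("nadh", function(x) standardGeneric("nadh"))

#' @rdname TPEFField-class
#' @export
setGeneric("fad", function(x) standardGeneric("fad"))

#' @rdname TPEFField-class
#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))

#' @rdname TPEFField-class
#' @export
setGeneric("fieldMeta", function(x) standardGeneric("fieldMeta"))

#' @rdname TPEFField-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname RedoxMap-class
#' @param x a package object
#' @export
setGeneric("redoxValues", function(x) standardGeneric("redoxValues"))

#' @rdname RedoxMap-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname DecayStack-class
#' @param x a package object
#' @export
setGeneric("decayCounts", function(x) standardGeneric("decayCounts"))

#' @rdname DecayStack-class
#' @export
setGeneric("binWidthNs", function(x) standardGeneric("binWidthNs"))

#' @rdname GaussianBasis-class
#' @param x a package object
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))

#' @rdname GaussianBasis-class
#' @export
setGeneric("componentSds", function(x) standardGeneric("componentSds"))

#' @rdname GaussianBasis-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
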