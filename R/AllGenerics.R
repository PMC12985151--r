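#' @rdname SSRPanel-class
#' @param x an object
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname SSRPanel-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypeTable-class
#' @param x an object
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))
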