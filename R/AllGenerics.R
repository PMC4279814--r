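#' @rdname DiscordantPairs-class
#' @param x a `DiscordantPairs` object.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname LibraryStats-class
#' @param x an object carrying library statistics.
#' @export
setGeneric("libStats", function(x) standardGeneric("libStats"))

#' @rdname TranspositionCalls-class
#' @param x a `TranspositionCalls` object.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname TEGenome-class
#' @param x a `TEGenome` object.
#' @export
setGeneric("refGenome", function(x) standardGeneric("refGenome"))

#' @rdname TEGenome-class
#' @export
setGeneric("teAnnotation", function(x) standardGeneric("teAnnotation"))

#' @rdname TranspositionTruth-class
#' @param x a `TranspositionTruth` object.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname TranspositionTruth-class
#' @export
setGeneric("modifiedGenome", function(x) standardGeneric("modifiedGenome"))
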