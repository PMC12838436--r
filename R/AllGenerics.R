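#' @rdname LongReadSet-class
#' @param x,object A LongReadSet.
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname LongReadSet-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname StrProfile-class
#' @export
setGeneric("readCalls", function(x) standardGeneric("readCalls"))

#' @rdname StrProfile-class
#' @export
setGeneric("profileSummary", function(x) standardGeneric("profileSummary"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("motifLabel", function(x) standardGeneric("motifLabel"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("mosaicFraction", function(x) standardGeneric("mosaicFraction"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("junctionsUsed", function(x) standardGeneric("junctionsUsed"))
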