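#' @rdname AnnotatedMitogenome-class
#' @param x An object.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("hasSequence", function(x) standardGeneric("hasSequence"))

#' @rdname CodonUsageTable-class
#' @param x An object.
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))

#' @rdname CodonUsageTable-class
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' @rdname CodonUsageTable-class
#' @export
setGeneric("rscuValues", function(x) standardGeneric("rscuValues"))

#' @rdname CodonUsageTable-class
#' @export
setGeneric("stopTally", function(x) standardGeneric("stopTally"))

#' @rdname GeneOrder-class
#' @param x An object.
#' @export
setGeneric("orderGenes", function(x) standardGeneric("orderGenes"))

#' @rdname GeneOrder-class
#' @export
setGeneric("orderSigns", function(x) standardGeneric("orderSigns"))
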