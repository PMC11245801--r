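#' @rdname AnnotatedMitogenome-class
#' @aliases genomeLength,AnnotatedMitogenome-method
#' @export
setMethod("genomeLength", "AnnotatedMitogenome", function(x) x@genomeLength)

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("genomeSequence", "AnnotatedMitogenome", function(x) x@sequence)

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("geneFeatures", "AnnotatedMitogenome", function(x) x@features)

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("isCircular", "AnnotatedMitogenome", function(x) x@circular)

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("genomeLabel", "AnnotatedMitogenome", function(x) x@label)

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("hasSequence", "AnnotatedMitogenome",
          function(x) !is.na(x@sequence))

setMethod("show", "AnnotatedMitogenome", function(object) {
    ft <- object@features
    cat("AnnotatedMitogenome '", object@label, "'\n", sep = "")
    cat("  length: ", object@genomeLength, " bp (",
        if (object@circular) "circular" else "linear", ", ",
        if (hasSequence(object)) "sequence present" else "coordinates-only",
        ")\n", sep = "")
    cls <- table(factor(ft$feature_class, levels = VALID_CLASSES))
    cat("  features: ", nrow(ft), " (", paste(names(cls), cls, sep = ":",
        collapse = ", "), ")\n", sep = "")
    invisible(object)
})

#' @rdname CodonUsageTable-class
#' @export
setMethod("codonCounts", "CodonUsageTable", function(x) x@counts)

#' @rdname CodonUsageTable-class
#' @export
setMethod("familyCounts", "CodonUsageTable", function(x) x@aaCounts)

#' @rdname CodonUsageTable-class
#' @export
setMethod("rscuValues", "CodonUsageTable", function(x) x@rscu)

#' @rdname CodonUsageTable-class
#' @export
setMethod("stopTally", "CodonUsageTable", function(x) x@stopTally)

setMethod("show", "CodonUsageTable", function(object) {
    cat("CodonUsageTable (translation table ", object@tableId, ", ",
        if (object@mergedFamilies) "merged" else "split",
        " Leu/Ser families)\n", sep = "")
    cat("  ", sum(object@counts), " codons in ", length(object@aaCounts),
        " families; ", sum(object@stopTally), " stop signals\n", sep = "")
    top <- sort(object@rscu, decreasing = TRUE)
    top <- top[!is.na(top)][seq_len(min(5L, sum(!is.na(object@rscu))))]
    cat("  top RSCU:", paste(names(top), round(top, 3), sep = "=",
        collapse = ", "), "\n")
    invisible(object)
})

#' @rdname GeneOrder-class
#' @export
setMethod("orderGenes", "GeneOrder", function(x) x@genes)

#' @rdname GeneOrder-class
#' @export
setMethod("orderSigns", "GeneOrder", function(x) x@orientation)

setMethod("show", "GeneOrder", function(object) {
    cat("GeneOrder '", object@label, "' (", length(object@genes),
        " genes, ", if (object@circular) "circular" else "linear", ")\n",
        sep = "")
    cat(" ", formatGeneOrder(object), "\n")
    invisible(object)
})

setMethod("show", "MitogenomeProfile", function(object) {
    cat("MitogenomeProfile for '", object@identity$label, "'\n", sep = "")
    cat("  length ", object@identity$genome_length, " bp, ",
        object@identity$n_genes, " genes\n", sep = "")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
    invisible(object)
})

#' Feature lengths implied by coordinates
#'
#' Length of each annotated feature in bp, honouring origin-wrapping
#' features on circular genomes (`genomeLength - start + 1 + end`).
#'
#' @param genome An [AnnotatedMitogenome-class] object.
#' @return Named integer vector of lengths, one per feature.
#' @export
featureLengths <- function(genome) {
    ft <- geneFeatures(genome)
    setNames(as.integer(.featureLength(ft$start, ft$end, ft$wraps_origin,
                                       genomeLength(genome))), ft$gene)
}

#' Total annotated length per feature class
#'
#' Sums feature lengths (overlaps not deduplicated, so class totals equal
#' the simple sums of the per-gene lengths) for each class present.
#'
#' @param genome An [AnnotatedMitogenome-class] object.
#' @return Named integer vector over the classes present (PCG, tRNA, rRNA, CR).
#' @export
featureClassLengths <- function(genome) {
    ft <- geneFeatures(genome)
    len <- featureLengths(genome)
    out <- tapply(len, factor(ft$feature_class, levels = VALID_CLASSES), sum)
    out <- out[!is.na(out)]
    setNames(as.integer(out), names(out))
}
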