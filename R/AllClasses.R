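#' @import methods
#' @importFrom stats setNames
NULL

VALID_CLASSES <- c("PCG", "tRNA", "rRNA", "CR")
VALID_STRANDS <- c("F", "R")

.emptyFeatures <- function() {
    data.frame(gene = character(), feature_class = character(),
               strand = character(), start = integer(), end = integer(),
               wraps_origin = logical(), partial = logical(),
               start_codon = character(), stop_codon = character(),
               stringsAsFactors = FALSE)
}

#' AnnotatedMitogenome: a circular mitochondrial genome with gene features
#'
#' Central container of the package: a (usually circular) mitochondrial
#' genome of known length, an optional nucleotide sequence, and an ordered
#' table of strand-aware gene features with 1-based inclusive coordinates.
#' When no sequence is available the object is in "coordinates-only" mode
#' and only structural analyses (junctions, spacers, control-region
#' inference, gene order) are possible.
#'
#' @slot sequence Character scalar over A,C,G,T,N, or `NA_character_` in
#'   coordinates-only mode.
#' @slot genomeLength Integer scalar, total genome length in bp.
#' @slot circular Logical scalar; mitogenomes are circular by default.
#' @slot features A `data.frame` with columns `gene`, `feature_class`
#'   (PCG/tRNA/rRNA/CR), `strand` (F/R), `start`, `end` (1-based inclusive),
#'   `wraps_origin`, `partial`, and optional annotated `start_codon` /
#'   `stop_codon`, sorted by `start`.
#' @slot label Character scalar used in reports.
#'
#' @export
setClass("AnnotatedMitogenome",
    representation(sequence = "character", genomeLength = "integer",
                   circular = "logical", features = "data.frame",
                   label = "character"),
    prototype(sequence = NA_character_, genomeLength = 0L, circular = TRUE,
              features = .emptyFeatures(), label = "mitogenome"))

.featureLength <- function(start, end, wraps, genomeLength) {
    ifelse(wraps, genomeLength - start + 1L + end, end - start + 1L)
}

setValidity("AnnotatedMitogenome", function(object) {
    msgs <- character()
    ft <- object@features
    need <- c("gene", "feature_class", "strand", "start", "end", "wraps_origin")
    if (!all(need %in% names(ft)))
        return(paste("features must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(ft$gene))
        msgs <- c(msgs, "duplicate gene names in features")
    if (nrow(ft)) {
        if (!all(ft$feature_class %in% VALID_CLASSES))
            msgs <- c(msgs, "feature_class must be one of PCG, tRNA, rRNA, CR")
        if (!all(ft$strand %in% VALID_STRANDS))
            msgs <- c(msgs, "strand must be F or R")
        if (any(ft$start < 1L) || any(ft$end < 1L))
            msgs <- c(msgs, "coordinates are 1-based; start/end must be >= 1")
        if (any(!ft$wraps_origin & ft$start > ft$end))
            msgs <- c(msgs, "start > end only allowed for wraps_origin features")
        if (any(ft$end > object@genomeLength) || any(ft$start > object@genomeLength))
            msgs <- c(msgs, "feature coordinates exceed genomeLength")
        if (is.unsorted(ft$start))
            msgs <- c(msgs, "features must be sorted by start")
    }
    if (!is.na(object@sequence) &&
        nchar(object@sequence) != object@genomeLength)
        msgs <- c(msgs, "sequence length disagrees with genomeLength")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CodonUsageTable: pooled codon counts, RSCU and start/stop classification
#'
#' Codon usage over the protein-coding genes of one mitogenome under a
#' mitochondrial genetic code: per-codon counts, synonymous-family
#' assignment (Leu and Ser split into their two families unless merged),
#' family totals, RSCU values, a separate stop-codon tally, and the
#' per-gene start/stop classification.
#'
#' @slot counts Named integer vector over the 60-62 sense codons.
#' @slot familyOf Named character vector mapping codon to synonymous family.
#' @slot aaCounts Named integer vector of family totals.
#' @slot rscu Named numeric vector of RSCU values (NA for empty families).
#' @slot stopTally Named integer vector counting complete stop triplets and
#'   incomplete tails ("T", "TA") across genes.
#' @slot perGeneStart,perGeneStop Named character vectors, one entry per PCG.
#' @slot tableId Integer NCBI translation table identifier.
#' @slot mergedFamilies Logical; TRUE when Leu/Ser families were merged.
#'
#' @export
setClass("CodonUsageTable",
    representation(counts = "integer", familyOf = "character",
                   aaCounts = "integer", rscu = "numeric",
                   stopTally = "integer", perGeneStart = "character",
                   perGeneStop = "character", tableId = "integer",
                   mergedFamilies = "logical"))

setValidity("CodonUsageTable", function(object) {
    msgs <- character()
    if (!all(names(object@counts) %in% names(object@familyOf)))
        msgs <- c(msgs, "every counted codon needs a family")
    fam <- object@familyOf[names(object@counts)]
    tot <- tapply(object@counts, fam, sum)
    if (length(object@aaCounts) &&
        !isTRUE(all.equal(as.integer(tot[names(object@aaCounts)]),
                          unname(object@aaCounts))))
        msgs <- c(msgs, "aaCounts disagree with summed codon counts")
    if (any(object@rscu < 0, na.rm = TRUE))
        msgs <- c(msgs, "RSCU values must be non-negative")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' GeneOrder: a signed (linearized) gene order
#'
#' An ordered list of gene names with orientations, used for rearrangement
#' comparison between mitogenomes. Orders are usually produced by
#' [linearizeOrder()], which rotates the circular order to a shared anchor
#' gene (cox1 by convention).
#'
#' @slot genes Character vector of unique gene names.
#' @slot orientation Character vector of "+" / "-" matching `genes`.
#' @slot circular Logical; whether the order represents a circular molecule.
#' @slot label Identifier used in comparison reports.
#'
#' @export
setClass("GeneOrder",
    representation(genes = "character", orientation = "character",
                   circular = "logical", label = "character"),
    prototype(circular = TRUE, label = "order"))

setValidity("GeneOrder", function(object) {
    msgs <- character()
    if (!length(object@genes)) msgs <- c(msgs, "gene order must be non-empty")
    if (anyDuplicated(object@genes)) msgs <- c(msgs, "gene names must be unique")
    if (length(object@orientation) != length(object@genes))
        msgs <- c(msgs, "orientation must match genes in length")
    if (length(object@orientation) && !all(object@orientation %in% c("+", "-")))
        msgs <- c(msgs, "orientation entries must be '+' or '-'")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MitogenomeProfile: aggregated analysis profile of one mitogenome
#'
#' The machine-readable product of [profileMitogenome()]: identity block,
#' composition table, codon usage, per-gene start/stop codons, spacer
#' summary, inferred control regions and the linearized gene order. Blocks
#' that need a sequence are flagged absent in coordinates-only mode.
#'
#' @slot identity,composition,codonUsage,startStop,spacers,controlRegions,geneOrder,flags
#'   See [profileMitogenome()].
#' @export
setClass("MitogenomeProfile",
    representation(identity = "list", composition = "ANY",
                   codonUsage = "ANY", startStop = "ANY", spacers = "ANY",
                   controlRegions = "ANY", geneOrder = "ANY",
                   flags = "character"))
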