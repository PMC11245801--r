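#' The deep-sea sea cucumber mitogenome annotation shipped with the package
#'
#' The published gene annotation of the *Benthodytes* sp. Gxx-2023
#' mitochondrial genome (GenBank OR992091; 17,386 bp, circular): 13
#' protein-coding genes, 22 tRNAs and 2 rRNAs with strand, 1-based
#' inclusive coordinates and annotated start/stop codons, as a
#' coordinates-only [AnnotatedMitogenome-class]. The deposited nucleotide
#' sequence is not redistributed; fetch it from GenBank and attach it via
#' the `sequence` argument of [parseFeatureTable()] to unlock the
#' sequence-dependent analyses.
#'
#' @return An [AnnotatedMitogenome-class] in coordinates-only mode.
#' @examples
#' g <- benthodytesAnnotation()
#' spacerSummary(g)$n_spacers   # 22
#' @export
benthodytesAnnotation <- function() {
    parseFeatureTable(system.file("extdata",
                                  "benthodytes_gxx2023_features.tsv",
                                  package = "mitoprofile", mustWork = TRUE),
                      label = "Benthodytes sp. Gxx-2023 (OR992091)")
}

#' Generator specification mirroring the shipped annotation
#'
#' Builds a [genomeSpec()] whose gene inventory (names, classes, strands,
#' lengths, start codons and complete stop codons) and junction plan
#' (every spacer, overlap and the 1-bp wrap gap) reproduce the shipped
#' *Benthodytes* sp. Gxx-2023 annotation exactly, so simulated genomes
#' share its full structural layout — including the two long control-region
#' gaps of 882 and 1,153 bp — while the sequence itself is synthetic.
#' Incomplete stop codons arise automatically for the three genes whose
#' length is not divisible by 3 (cox2, nad4, cytb).
#'
#' @param baseFreqs,codonBias,crFreqs,crMinLen,code,label Passed to
#'   [genomeSpec()]; `baseFreqs` defaults to the study genome's base
#'   composition, `crFreqs` to its AT-richer control-region composition.
#' @return A `"GenomeSpec"` list.
#' @export
benthodytesGenomeSpec <- function(baseFreqs = .defaultBaseFreqs,
                                  codonBias = NULL,
                                  crFreqs = c(A = 0.3096, C = 0.1686,
                                              G = 0.0988, T = 0.4231),
                                  crMinLen = 500L, code = geneticCode(),
                                  label = "synthetic-gxx2023") {
    g <- benthodytesAnnotation()
    ft <- geneFeatures(g)
    jn <- junctions(g)
    inv <- data.frame(name = ft$gene, class = ft$feature_class,
                      strand = ft$strand,
                      length = as.integer(featureLengths(g)),
                      start_codon = ft$start_codon,
                      stop_codon = ifelse(ft$stop_codon %in% c("T", "TA"),
                                          NA_character_, ft$stop_codon),
                      stringsAsFactors = FALSE)
    plan <- jn$gap[match(inv$name, jn$upstream)]
    genomeSpec(inv, plan, baseFreqs = baseFreqs, codonBias = codonBias,
               crFreqs = crFreqs, crMinLen = crMinLen, code = code,
               label = label)
}
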