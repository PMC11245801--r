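AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' A mitochondrial genetic code
#'
#' Wraps an NCBI translation table (via Biostrings) into the structure
#' the codon-usage operations consume. The default, table 9, is the
#' echinoderm/flatworm mitochondrial code: AGA/AGG encode Ser, ATA Ile,
#' AAA Asn and TGA Trp, so it has 62 sense codons and only 2 stops
#' (TAA, TAG).
#'
#' @param tableId NCBI translation table identifier (default 9).
#' @return A list with elements `tableId`, `codonToAA` (named character,
#'   64 DNA codons, "*" for stops), `startCodons`, `stopCodons`.
#' @examples
#' geneticCode()$codonToAA[c("AGA", "ATA", "TGA")]  # "S" "I" "W"
#' @export
geneticCode <- function(tableId = 9L) {
    map <- Biostrings::getGeneticCode(as.character(tableId))
    list(tableId = as.integer(tableId),
         codonToAA = setNames(as.character(map), names(map)),
         startCodons = union("ATG", attr(map, "alt_init_codons")),
         stopCodons = names(map)[map == "*"])
}

#' Synonymous-family assignment for each sense codon
#'
#' Families follow mitochondrial codon-usage convention: one family per
#' amino acid, with Leu split into Leu-UUR (TTA/TTG) and Leu-CUN, and Ser
#' into Ser-UCN (TCN) and Ser-AGN, matching how RSCU is conventionally
#' plotted; `merged = TRUE` collapses each pair into a single family for
#' sensitivity analyses.
#'
#' @param code A [geneticCode()] list.
#' @param merged Merge the split Leu/Ser families.
#' @return Named character vector: codon -> family label.
#' @export
codonFamilies <- function(code = geneticCode(), merged = FALSE) {
    aa <- code$codonToAA
    sense <- names(aa)[aa != "*"]
    fam <- AA3[aa[sense]]
    names(fam) <- sense
    if (!merged) {
        leu <- sense[aa[sense] == "L"]
        fam[leu] <- ifelse(substr(leu, 1L, 2L) == "TT", "Leu-UUR", "Leu-CUN")
        ser <- sense[aa[sense] == "S"]
        fam[ser] <- ifelse(substr(ser, 1L, 2L) == "AG", "Ser-AGN", "Ser-UCN")
    }
    fam
}

#' Split a coding sequence into codons
#'
#' @param cds Nucleotide string, length >= 3.
#' @return A list: `codons` (character vector of complete triplets read
#'   from position 1) and `tail` (the trailing 0-, 1- or 2-base
#'   remainder, possibly an incomplete stop codon).
#' @examples
#' splitCodons("ATGAAAT")  # 2 codons, tail "T"
#' @export
splitCodons <- function(cds) {
    len <- nchar(cds)
    if (len < 3L) stop("coding sequence shorter than one codon")
    n <- len %/% 3L
    starts <- 3L * (seq_len(n) - 1L) + 1L
    list(codons = substring(cds, starts, starts + 2L),
         tail = substring(cds, 3L * n + 1L, len))
}

#' Classify the start and stop codon of a coding sequence
#'
#' The start is the first triplet, reported verbatim. The stop is the
#' final complete triplet when it is a stop codon of the code and the
#' sequence ends on a codon boundary; otherwise a non-empty trailing
#' remainder is reported as an incomplete stop ("T" or "TA", completed to
#' TAA by post-transcriptional polyadenylation). A sequence ending in a
#' non-stop complete triplet is flagged anomalous.
#'
#' @param cds Coding-strand sequence of a protein-coding gene.
#' @param code A [geneticCode()] list.
#' @return List: `start`, `stop`, `anomalous` (logical).
#' @examples
#' classifyStartStop("ATGAAATAA")$stop   # "TAA"
#' classifyStartStop("ATGAAAT")$stop     # incomplete "T"
#' @export
classifyStartStop <- function(cds, code = geneticCode()) {
    sc <- splitCodons(cds)
    start <- sc$codons[1L]
    last <- sc$codons[length(sc$codons)]
    if (nzchar(sc$tail))
        list(start = start, stop = sc$tail, anomalous = FALSE)
    else if (last %in% code$stopCodons)
        list(start = start, stop = last, anomalous = FALSE)
    else
        list(start = start, stop = last, anomalous = TRUE)
}

#' Translate a coding sequence
#'
#' @param cds Nucleotide string.
#' @param code A [geneticCode()] list.
#' @return Amino-acid string ("*" terminator, "X" for codons with N);
#'   a trailing incomplete codon is dropped.
#' @export
translateCDS <- function(cds, code = geneticCode()) {
    sc <- splitCodons(cds)
    aa <- code$codonToAA[sc$codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

#' Pooled codon usage of all protein-coding genes
#'
#' Extracts each PCG's coding sequence, splits it into codons, and pools
#' counts across genes. Complete stop triplets and incomplete stop tails
#' are excluded from the amino-acid counts and kept in a separate stop
#' tally; codons containing N are dropped. Per-gene start/stop
#' classification ([classifyStartStop()]) is recorded alongside.
#'
#' @param genome A sequence-bearing [AnnotatedMitogenome-class] with PCGs.
#' @param code A [geneticCode()] list (default translation table 9).
#' @param merged Merge Leu/Ser split families (see [codonFamilies()]).
#' @return A [CodonUsageTable-class] object.
#' @export
countCodons <- function(genome, code = geneticCode(), merged = FALSE) {
    ft <- geneFeatures(genome)
    pcgs <- ft$gene[ft$feature_class == "PCG"]
    if (!length(pcgs)) stop("no PCG features in genome")
    fam <- codonFamilies(code, merged = merged)
    counts <- setNames(integer(length(fam)), names(fam))
    stops <- setNames(integer(length(code$stopCodons) + 2L),
                      c(code$stopCodons, "T", "TA"))
    starts <- setNames(character(length(pcgs)), pcgs)
    ends <- setNames(character(length(pcgs)), pcgs)
    for (g in pcgs) {
        cds <- extractGeneSequence(genome, g)
        sc <- splitCodons(cds)
        cl <- classifyStartStop(cds, code)
        starts[g] <- cl$start; ends[g] <- cl$stop
        if (nzchar(sc$tail) && sc$tail %in% names(stops))
            stops[sc$tail] <- stops[sc$tail] + 1L
        tab <- table(sc$codons)
        for (cd in names(tab)) {
            if (cd %in% code$stopCodons)
                stops[cd] <- stops[cd] + as.integer(tab[[cd]])
            else if (cd %in% names(counts))
                counts[cd] <- counts[cd] + as.integer(tab[[cd]])
            # codons containing N fall through and are dropped
        }
    }
    aaCounts <- tapply(counts, fam[names(counts)], sum)
    aaCounts <- setNames(as.integer(aaCounts), names(aaCounts))
    tab <- new("CodonUsageTable", counts = counts, familyOf = fam,
               aaCounts = aaCounts, rscu = numeric(), stopTally = stops,
               perGeneStart = starts, perGeneStop = ends,
               tableId = code$tableId, mergedFamilies = merged)
    tab@rscu <- computeRSCU(tab)
    validObject(tab)
    tab
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = count(c) x family_size / family_total: the observed count of
#' a codon divided by the count expected if all codons of its synonymous
#' family were used equally. Values over a family average 1 whenever the
#' family was observed at all; families with zero total are reported as
#' NA (flagged null).
#'
#' @param table A [CodonUsageTable-class] object.
#' @return Named numeric vector, codon -> RSCU.
#' @export
computeRSCU <- function(table) {
    counts <- table@counts
    fam <- table@familyOf[names(counts)]
    size <- table(fam)
    total <- tapply(counts, fam, sum)
    out <- ifelse(total[fam] > 0,
                  counts * as.numeric(size[fam]) / as.numeric(total[fam]),
                  NA_real_)
    setNames(as.numeric(out), names(counts))
}

#' Amino-acid usage frequencies
#'
#' Family counts as percentages of all counted (non-stop) codons.
#'
#' @param table A [CodonUsageTable-class] object.
#' @return A `data.frame` with columns `family`, `count`, `pct`, sorted
#'   by decreasing count.
#' @export
aaFrequencies <- function(table) {
    cnt <- familyCounts(table)
    out <- data.frame(family = names(cnt), count = as.integer(cnt),
                      pct = 100 * as.integer(cnt) / sum(cnt),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$family), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-gene start/stop codon table
#'
#' With a sequence, classification is computed from each PCG's coding
#' sequence; in coordinates-only mode the annotated `start_codon` /
#' `stop_codon` columns of the feature table are used instead.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @param code A [geneticCode()] list.
#' @return A `data.frame` with columns `gene`, `start_codon`,
#'   `stop_codon`, `source` ("sequence" or "annotation").
#' @export
startStopTable <- function(genome, code = geneticCode()) {
    ft <- geneFeatures(genome)
    ft <- ft[ft$feature_class == "PCG", , drop = FALSE]
    if (!nrow(ft)) stop("no PCG features in genome")
    if (hasSequence(genome)) {
        cl <- lapply(ft$gene, function(g)
            classifyStartStop(extractGeneSequence(genome, g), code))
        data.frame(gene = ft$gene,
                   start_codon = vapply(cl, `[[`, "", "start"),
                   stop_codon = vapply(cl, `[[`, "", "stop"),
                   source = "sequence", stringsAsFactors = FALSE)
    } else {
        if (all(is.na(ft$start_codon)))
            stop("coordinates-only genome without annotated start/stop codons")
        data.frame(gene = ft$gene, start_codon = ft$start_codon,
                   stop_codon = ft$stop_codon, source = "annotation",
                   stringsAsFactors = FALSE)
    }
}

#' RSCU bar chart
#'
#' Grouped bar chart of RSCU values per synonymous family, the standard
#' codon-usage figure of mitogenome papers. Requires ggplot2.
#'
#' @param table A [CodonUsageTable-class] object.
#' @return A ggplot object.
#' @export
plotRSCU <- function(table) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotRSCU requires the ggplot2 package")
    df <- data.frame(codon = names(table@counts),
                     family = table@familyOf[names(table@counts)],
                     rscu = table@rscu, stringsAsFactors = FALSE)
    df <- df[!is.na(df$rscu), , drop = FALSE]
    df$family <- factor(df$family, levels = sort(unique(df$family)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data[["family"]],
                                     y = .data[["rscu"]],
                                     fill = .data[["codon"]])) +
        ggplot2::geom_col(position = "stack", colour = "grey30",
                          linewidth = 0.2) +
        ggplot2::labs(x = NULL, y = "RSCU") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x =
            ggplot2::element_text(angle = 60, hjust = 1),
            legend.position = "none")
}
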