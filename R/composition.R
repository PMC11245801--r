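#' Base composition and skew statistics of a nucleotide sequence
#'
#' Counts A/C/G/T/N, percentages, AT% and GC%, and the strand-asymmetry
#' skews AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C). All
#' percentages are carried at full precision; rounding is left to report
#' writers. A skew whose denominator is zero is reported as `NA` (flagged
#' null), never as 0.
#'
#' @param seq Non-empty nucleotide string over A,C,G,T,N.
#' @return A one-row `data.frame` with columns `n`, `A`, `C`, `G`, `T`,
#'   `N`, `pct_T`, `pct_C`, `pct_A`, `pct_G`, `pct_AT`, `pct_GC`,
#'   `at_skew`, `gc_skew`.
#' @examples
#' baseComposition("AACGT")  # AT% 60, AT-skew 1/3, GC-skew 0
#' @export
baseComposition <- function(seq) {
    if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
        stop("empty sequence: nothing to count")
    seq <- .checkSequence(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    cnt <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
    n <- length(ch)
    A <- cnt[["A"]]; C <- cnt[["C"]]; G <- cnt[["G"]]; T <- cnt[["T"]]
    skew <- function(p, q) if (p + q == 0L) NA_real_ else (p - q) / (p + q)
    data.frame(n = n, A = A, C = C, G = G, T = T, N = cnt[["N"]],
               pct_T = 100 * T / n, pct_C = 100 * C / n,
               pct_A = 100 * A / n, pct_G = 100 * G / n,
               pct_AT = 100 * (A + T) / n, pct_GC = 100 * (G + C) / n,
               at_skew = skew(A, T), gc_skew = skew(G, C),
               row.names = NULL)
}

.classSequence <- function(genome, feature_class, codingStrand = TRUE) {
    ft <- geneFeatures(genome)
    sel <- ft$gene[ft$feature_class == feature_class]
    if (!length(sel))
        stop("no features of class '", feature_class, "' in genome")
    pieces <- vapply(sel, function(g) {
        if (codingStrand) extractGeneSequence(genome, g)
        else {
            i <- match(g, ft$gene)
            substring(genomeSequence(genome), ft$start[i], ft$end[i])
        }
    }, character(1L))
    paste(pieces, collapse = "")
}

#' Composition statistics for one feature class
#'
#' Statistics over the concatenation, in genome order, of the
#' coding-strand sequences of every feature of the class. Overlapping
#' genes contribute their shared bases to each gene (no deduplication), so
#' the class length equals the simple sum of gene lengths. Control-region
#' statistics require CR features; when the annotation has none, add them
#' with [addInferredControlRegions()].
#'
#' @param genome A sequence-bearing [AnnotatedMitogenome-class].
#' @param feature_class One of "PCG", "tRNA", "rRNA", "CR".
#' @param codingStrand Use each gene's sense sequence (default). FALSE
#'   takes the deposited-strand slice instead, for sensitivity checks.
#' @return A one-row `data.frame` as in [baseComposition()].
#' @export
classComposition <- function(genome, feature_class, codingStrand = TRUE) {
    baseComposition(.classSequence(genome, feature_class, codingStrand))
}

#' Composition by codon position across all protein-coding genes
#'
#' Pools the bases at codon positions 1, 2 and 3 over all protein-coding
#' genes. The default convention (`framing = "pooled"`, the one used by
#' descriptive mitogenome tables) concatenates the coding-strand
#' sequences of all PCGs in genome order and partitions the concatenation
#' into triplets, so every base is included and each position holds
#' exactly total/3 bases whenever the pooled length is divisible by 3.
#' `framing = "per-gene"` restarts the reading frame at each annotated
#' start and uses only complete codons, excluding the bases of incomplete
#' terminal (stop) codons.
#'
#' @param genome A sequence-bearing [AnnotatedMitogenome-class].
#' @param framing "pooled" (default) or "per-gene"; see Details.
#' @return A three-row `data.frame` (positions 1-3) as in
#'   [baseComposition()], with a `position` column prepended.
#' @export
codonPositionComposition <- function(genome,
                                     framing = c("pooled", "per-gene")) {
    framing <- match.arg(framing)
    ft <- geneFeatures(genome)
    pcgs <- ft$gene[ft$feature_class == "PCG"]
    if (!length(pcgs)) stop("no PCG features in genome")
    chunks <- lapply(pcgs, function(g) {
        cds <- extractGeneSequence(genome, g)
        if (framing == "per-gene")
            cds <- substring(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
        strsplit(cds, "", fixed = TRUE)[[1L]]
    })
    if (framing == "pooled") {
        ch <- unlist(chunks)
        pos <- (seq_along(ch) - 1L) %% 3L + 1L
        pooled <- split(ch, pos)
    } else {
        pooled <- lapply(1:3, function(p)
            unlist(lapply(chunks, function(ch)
                ch[(seq_along(ch) - 1L) %% 3L + 1L == p])))
    }
    out <- do.call(rbind, lapply(1:3, function(p)
        baseComposition(paste(pooled[[p]], collapse = ""))))
    cbind(position = 1:3, out)
}

#' Composition report table for a whole mitogenome
#'
#' The standard descriptive table: one row each for the whole genome, the
#' pooled PCGs, the three codon positions, tRNAs, rRNAs and control
#' regions, with a `number` column (units pooled in the row) and the
#' row length as a percentage of genome length. Rows whose class is
#' absent are emitted as NA with a note in the `flag` column.
#'
#' @param genome A sequence-bearing [AnnotatedMitogenome-class].
#' @param inferCR When the annotation has no CR features, infer control
#'   regions from long gaps (see [inferControlRegions()]) before computing
#'   the control-region row (default TRUE).
#' @param minCRLength Minimum gap length for CR inference, bp.
#' @return A `data.frame` with columns `row`, `number`, then the
#'   [baseComposition()] columns, `pct_of_genome`, and `flag`.
#' @export
compositionTable <- function(genome, inferCR = TRUE, minCRLength = 500L) {
    if (!hasSequence(genome))
        stop("composition requires a sequence-bearing genome")
    ft <- geneFeatures(genome)
    if (inferCR && !any(ft$feature_class == "CR"))
        genome <- tryCatch(addInferredControlRegions(genome,
                                                     minLen = minCRLength),
                           error = function(e) genome)
    ft <- geneFeatures(genome)
    nOf <- function(cls) sum(ft$feature_class == cls)

    narow <- function(flag) {
        out <- baseComposition("A")   # template for column layout
        out[1L, ] <- NA
        cbind(out, flag = flag)
    }
    tryRow <- function(expr, what) {
        tryCatch(cbind(expr, flag = NA_character_),
                 error = function(e) narow(conditionMessage(e)))
    }
    rows <- list(
        Genome = cbind(number = 1L,
                       tryRow(baseComposition(genomeSequence(genome)))),
        PCGs = cbind(number = nOf("PCG"), tryRow(classComposition(genome, "PCG"))))
    pos <- tryCatch(codonPositionComposition(genome), error = function(e) NULL)
    for (p in 1:3) {
        r <- if (is.null(pos)) narow("no PCGs")
             else cbind(pos[p, setdiff(names(pos), "position")],
                        flag = NA_character_)
        rows[[paste0("Position", p)]] <- cbind(number = r$n, r)
    }
    rows$tRNA <- cbind(number = nOf("tRNA"), tryRow(classComposition(genome, "tRNA")))
    rows$rRNA <- cbind(number = nOf("rRNA"), tryRow(classComposition(genome, "rRNA")))
    rows$`Control region` <- cbind(number = nOf("CR"),
                                   tryRow(classComposition(genome, "CR")))
    out <- do.call(rbind, rows)
    out <- cbind(row = names(rows), out)
    out$pct_of_genome <- 100 * out$n / genomeLength(genome)
    rownames(out) <- NULL
    out
}
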