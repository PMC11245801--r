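#' Signed intergenic junctions of an annotated mitogenome
#'
#' For every consecutive pair of genes (sorted by start, control-region
#' features excluded — they live inside the gaps being measured) the
#' signed gap `start(downstream) - end(upstream) - 1`: positive = spacer,
#' zero = abutting, negative = overlap. On circular genomes the wrap
#' junction (last gene back to the first through the origin) is appended
#' and flagged. Junction analysis assumes no gene spans the origin;
#' annotations are conventionally rotated so that none does.
#'
#' @param genome An [AnnotatedMitogenome-class] (sequence not required).
#' @return A `data.frame` with columns `upstream`, `downstream`, `gap`,
#'   `wrap`.
#' @examples
#' g <- annotatedMitogenome(
#'   rbind(geneFeature("gA", "PCG", "F", 1, 100),
#'         geneFeature("gB", "tRNA", "F", 101, 160)),
#'   genomeLength = 200)
#' junctions(g)  # gap 0, then wrap gap 40
#' @export
junctions <- function(genome) {
    ft <- geneFeatures(genome)
    ft <- ft[ft$feature_class != "CR", , drop = FALSE]
    if (nrow(ft) < 2L) stop("need at least two non-CR features")
    if (any(ft$wraps_origin))
        stop("junction analysis requires no gene to span the origin; ",
             "rotate the annotation first")
    n <- nrow(ft)
    for (j in 2:n) {
        i <- which(ft$end[seq_len(j - 1L)] >= ft$end[j])
        if (length(i))
            stop("nested features: '", ft$gene[j], "' lies inside '",
                 ft$gene[i[1L]], "'")
    }
    gaps <- ft$start[-1L] - ft$end[-n] - 1L
    out <- data.frame(upstream = ft$gene[-n], downstream = ft$gene[-1L],
                      gap = as.integer(gaps), wrap = FALSE,
                      stringsAsFactors = FALSE)
    if (isCircular(genome)) {
        wrapGap <- genomeLength(genome) - ft$end[n] + ft$start[1L] - 1L
        out <- rbind(out, data.frame(upstream = ft$gene[n],
                                     downstream = ft$gene[1L],
                                     gap = as.integer(wrapGap), wrap = TRUE))
    }
    rownames(out) <- NULL
    out
}

#' Maximal runs of genes joined with zero gap
#'
#' Maximal sets of two or more consecutive genes whose junction gaps are
#' all exactly 0 (no spacer, no overlap). The wrap junction is not
#' considered part of a run.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @return List of character vectors (gene names), possibly empty.
#' @export
zeroGapRuns <- function(genome) {
    jn <- junctions(genome)
    jn <- jn[!jn$wrap, , drop = FALSE]
    runs <- list(); cur <- character()
    for (i in seq_len(nrow(jn))) {
        if (jn$gap[i] == 0L) {
            if (!length(cur)) cur <- jn$upstream[i]
            cur <- c(cur, jn$downstream[i])
        } else if (length(cur)) {
            runs[[length(runs) + 1L]] <- cur; cur <- character()
        }
    }
    if (length(cur)) runs[[length(runs) + 1L]] <- cur
    runs
}

#' Spacer and overlap summary of an annotated mitogenome
#'
#' Classifies all junctions into spacers (gap > 0) and overlaps
#' (gap < 0), with totals, the largest of each (ties broken by genome
#' position, first wins) and the zero-gap runs. The wrap junction is
#' excluded from the spacer/overlap accounting by default, matching the
#' convention of descriptive mitogenome tables that list the gap before
#' each gene starting from the second; `includeWrap = TRUE` includes it.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @param includeWrap Count the wrap junction as a spacer/overlap.
#' @return A list with elements `n_spacers`, `total_spacer_bp`,
#'   `n_overlaps`, `total_overlap_bp`, `largest_spacer`,
#'   `largest_overlap` (each a list upstream/downstream/bp, or NULL),
#'   `zero_gap_runs`, `n_genes_in_zero_gap_runs`.
#' @export
spacerSummary <- function(genome, includeWrap = FALSE) {
    jn <- junctions(genome)
    if (!includeWrap) jn <- jn[!jn$wrap, , drop = FALSE]
    sp <- jn[jn$gap > 0L, , drop = FALSE]
    ov <- jn[jn$gap < 0L, , drop = FALSE]
    pick <- function(d, decreasing) {
        if (!nrow(d)) return(NULL)
        i <- which.max(if (decreasing) d$gap else -d$gap)  # first max wins
        list(upstream = d$upstream[i], downstream = d$downstream[i],
             bp = abs(d$gap[i]))
    }
    runs <- zeroGapRuns(genome)
    list(n_spacers = nrow(sp), total_spacer_bp = sum(sp$gap),
         n_overlaps = nrow(ov), total_overlap_bp = sum(abs(ov$gap)),
         largest_spacer = pick(sp, TRUE), largest_overlap = pick(ov, FALSE),
         zero_gap_runs = runs,
         n_genes_in_zero_gap_runs = length(unique(unlist(runs))))
}

#' Infer control regions from long intergenic gaps
#'
#' Mitochondrial control regions are non-coding and typically appear as
#' the longest unannotated stretches of the genome. Every junction
#' (including the wrap junction) whose gap is at least `minLen` becomes a
#' candidate control region with explicit 1-based inclusive coordinates.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @param minLen Minimum gap length in bp (default 500).
#' @return A `data.frame` with columns `name`, `start`, `end`, `length`,
#'   `after`, `before`, `wraps_origin`, sorted by position; zero rows when
#'   no gap reaches `minLen`.
#' @examples
#' g <- annotatedMitogenome(
#'   rbind(geneFeature("gA", "PCG", "F", 1, 100),
#'         geneFeature("gB", "tRNA", "F", 801, 860)),
#'   genomeLength = 900)
#' inferControlRegions(g)  # the 700-bp gap after gA
#' @export
inferControlRegions <- function(genome, minLen = 500L) {
    jn <- junctions(genome)
    jn <- jn[jn$gap >= minLen, , drop = FALSE]
    if (!nrow(jn))
        return(data.frame(name = character(), start = integer(),
                          end = integer(), length = integer(),
                          after = character(), before = character(),
                          wraps_origin = logical()))
    ft <- geneFeatures(genome)
    glen <- genomeLength(genome)
    res <- lapply(seq_len(nrow(jn)), function(i) {
        up <- ft[match(jn$upstream[i], ft$gene), ]
        dn <- ft[match(jn$downstream[i], ft$gene), ]
        if (!jn$wrap[i]) {
            data.frame(start = up$end + 1L, end = dn$start - 1L,
                       wraps_origin = FALSE)
        } else {
            s <- up$end + 1L; e <- dn$start - 1L
            if (s > glen) s <- s - glen           # gap entirely past origin
            data.frame(start = s, end = if (e >= 1L) e else glen,
                       wraps_origin = s > (if (e >= 1L) e else glen))
        }
    })
    out <- do.call(rbind, res)
    out$length <- as.integer(jn$gap)
    out$after <- jn$upstream; out$before <- jn$downstream
    out <- out[order(out$start), , drop = FALSE]
    out <- cbind(name = paste0("CR", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out[, c("name", "start", "end", "length", "after", "before",
            "wraps_origin")]
}

#' @rdname inferControlRegions
#' @details `addInferredControlRegions()` runs the inference and appends
#'   the resulting intervals to the genome as CR features, so that
#'   control-region composition can be computed on annotations (like most
#'   deposited mitogenomes) that do not list them.
#' @export
addInferredControlRegions <- function(genome, minLen = 500L) {
    cr <- inferControlRegions(genome, minLen = minLen)
    if (!nrow(cr)) return(genome)
    feats <- rbind(geneFeatures(genome),
                   do.call(rbind, lapply(seq_len(nrow(cr)), function(i)
                       geneFeature(cr$name[i], "CR", "F", cr$start[i],
                                   cr$end[i],
                                   wraps_origin = cr$wraps_origin[i]))))
    annotatedMitogenome(feats, genomeLength = genomeLength(genome),
                        sequence = genomeSequence(genome),
                        circular = isCircular(genome),
                        label = genomeLabel(genome))
}

#' Circular length-conservation identity
#'
#' On a circular genome with no nested genes, feature lengths, positive
#' gaps (wrap junction included) and overlaps partition the circle:
#' `sum(lengths) + sum(spacers) - sum(|overlaps|) = genome length`.
#' Returns the terms so callers can assert the identity exactly.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @return Named list: `sum_feature_bp` (non-CR), `sum_spacer_bp`
#'   (positive gaps incl. wrap), `sum_overlap_bp` (absolute),
#'   `lhs`, `genome_length`, `holds`.
#' @export
circularLengthIdentity <- function(genome) {
    ft <- geneFeatures(genome)
    ft <- ft[ft$feature_class != "CR", , drop = FALSE]
    len <- sum(.featureLength(ft$start, ft$end, ft$wraps_origin,
                              genomeLength(genome)))
    jn <- junctions(genome)
    sp <- sum(jn$gap[jn$gap > 0L])
    ov <- sum(abs(jn$gap[jn$gap < 0L]))
    lhs <- len + sp - ov
    list(sum_feature_bp = as.integer(len), sum_spacer_bp = as.integer(sp),
         sum_overlap_bp = as.integer(ov), lhs = as.integer(lhs),
         genome_length = genomeLength(genome),
         holds = lhs == genomeLength(genome))
}
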