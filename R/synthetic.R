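#' Base frequencies from AT content and skews
#'
#' Converts the descriptive parameterization (AT%, AT-skew, GC-skew) into
#' per-base probabilities: A = AT(1+skew)/2, T = AT(1-skew)/2, and
#' likewise for G/C.
#'
#' @param pctAT AT content as a percentage (0-100).
#' @param atSkew,gcSkew Skews in [-1, 1].
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @examples
#' composeBaseFreqs(67.86, -0.076, -0.164)
#' @export
composeBaseFreqs <- function(pctAT, atSkew = 0, gcSkew = 0) {
    at <- pctAT / 100; gc <- 1 - at
    c(A = at * (1 + atSkew) / 2, C = gc * (1 - gcSkew) / 2,
      G = gc * (1 + gcSkew) / 2, T = at * (1 - atSkew) / 2)
}

#' Random sequence with a target base composition
#'
#' I.i.d. draws from the given base frequencies; deterministic for a
#' fixed seed.
#'
#' @param length Sequence length, >= 1.
#' @param baseFreqs Named probabilities for A, C, G, T (normalized
#'   internally).
#' @param seed Optional integer seed; NULL uses the current RNG state.
#' @return Nucleotide string.
#' @export
generateSequenceWithComposition <- function(length, baseFreqs,
                                            seed = NULL) {
    stopifnot(length >= 1L)
    if (!is.null(seed)) set.seed(seed)
    bases <- c("A", "C", "G", "T")
    p <- baseFreqs[bases]
    if (anyNA(p)) stop("baseFreqs must name A, C, G and T")
    paste(sample(bases, length, replace = TRUE, prob = p / sum(p)),
          collapse = "")
}

.defaultBaseFreqs <- c(A = 0.3135, C = 0.1870, G = 0.1344, T = 0.3651)

#' Specification for a synthetic annotated mitogenome
#'
#' Describes a circular mitogenome to simulate: the gene inventory in
#' genome order (name, class, strand, length, and for PCGs the start
#' codon to plant and, for lengths divisible by 3, the complete stop
#' codon), the signed gap following each gene (the last entry is the wrap
#' gap back to the first gene), target base frequencies, and optional
#' per-codon weights steering codon bias within synonymous families.
#' Protein-coding genes whose length is 1 or 2 mod 3 are planted with an
#' incomplete stop ("T"/"TA"), emulating stops completed by
#' polyadenylation. The defaults for `baseFreqs` follow the base
#' composition typical of sea-cucumber mitogenomes (AT-rich with
#' negative skews).
#'
#' @param geneInventory `data.frame` with columns `name`, `class`
#'   (PCG/tRNA/rRNA), `strand` (F/R), `length`, optional `start_codon`
#'   (default ATG) and `stop_codon` (default TAA).
#' @param junctionPlan Integer vector, one signed gap per gene (after
#'   that gene), wrap gap last; negative = overlap with the next gene.
#' @param baseFreqs Named A/C/G/T probabilities for intergenic, tRNA and
#'   rRNA sequence.
#' @param codonBias Optional named non-negative weights over sense
#'   codons; unnamed codons get weight 0. NULL derives weights from
#'   `baseFreqs` (product over the codon's bases), so coding regions
#'   approximate the requested composition.
#' @param crFreqs Optional distinct base frequencies for gaps at least
#'   `crMinLen` long (control regions are typically AT-richer).
#' @param crMinLen Gap length from which `crFreqs` applies (default 500).
#' @param code A [geneticCode()] list used for PCG simulation.
#' @param label Genome label.
#' @return A list of class `"GenomeSpec"`.
#' @export
genomeSpec <- function(geneInventory, junctionPlan,
                       baseFreqs = .defaultBaseFreqs, codonBias = NULL,
                       crFreqs = NULL, crMinLen = 500L,
                       code = geneticCode(), label = "synthetic") {
    inv <- geneInventory
    stopifnot(all(c("name", "class", "strand", "length") %in% names(inv)))
    n <- nrow(inv)
    if (n < 1L) stop("empty gene inventory")
    if (length(junctionPlan) != n)
        stop("junctionPlan needs one gap per gene (wrap gap last)")
    if (any(inv$length < 1L)) stop("gene lengths must be >= 1")
    if (anyDuplicated(inv$name)) stop("duplicate gene names in inventory")
    if (abs(sum(baseFreqs) - 1) > 1e-6)
        stop("baseFreqs must sum to 1")
    pcg <- inv$class == "PCG"
    if (any(pcg & inv$length < 6L))
        stop("PCG lengths must be >= 6 (start plus stop signal)")
    if (is.null(inv$start_codon)) inv$start_codon <- NA_character_
    if (is.null(inv$stop_codon)) inv$stop_codon <- NA_character_
    inv$start_codon[pcg & is.na(inv$start_codon)] <- "ATG"
    inv$stop_codon[pcg & is.na(inv$stop_codon)] <- "TAA"
    nxt <- c(2:n, 1L)
    ov <- -pmin(junctionPlan, 0L)
    bad <- ov > 0 & ov >= pmin(inv$length, inv$length[nxt])
    if (any(bad))
        stop("infeasible junctionPlan: overlap after ",
             paste(inv$name[bad], collapse = ", "),
             " is at least as long as an adjacent gene")
    structure(list(geneInventory = inv,
                   junctionPlan = as.integer(junctionPlan),
                   baseFreqs = baseFreqs, codonBias = codonBias,
                   crFreqs = crFreqs, crMinLen = as.integer(crMinLen),
                   code = code, label = label),
              class = "GenomeSpec")
}

.sampleCodons <- function(n, weights, code) {
    if (n == 0L) return(character())
    sense <- names(code$codonToAA)[code$codonToAA != "*"]
    w <- weights[sense]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop("codonBias gives zero total weight")
    sample(sense, n, replace = TRUE, prob = w / sum(w))
}

# default codon weights: product of the target base frequencies over the
# codon's three bases, so coding regions approximate the requested
# composition even though they are drawn codon-wise
.codonWeightsFromFreqs <- function(baseFreqs, code) {
    sense <- names(code$codonToAA)[code$codonToAA != "*"]
    p <- baseFreqs / sum(baseFreqs)
    vapply(sense, function(cd) {
        b <- strsplit(cd, "", fixed = TRUE)[[1L]]
        prod(p[b])
    }, numeric(1L))
}

.simulateCDS <- function(len, startCodon, stopCodon, weights, code) {
    tail <- len %% 3L
    nBody <- (len - tail) %/% 3L - 1L - (tail == 0L)
    tailSeq <- c("", "T", "TA")[tail + 1L]
    paste0(startCodon,
           paste(.sampleCodons(nBody, weights, code), collapse = ""),
           if (tail == 0L) stopCodon else tailSeq)
}

#' Generate a synthetic annotated mitogenome with known ground truth
#'
#' Lays the gene inventory around the circle according to the junction
#' plan, simulates each gene's coding-strand sequence (PCGs codon by
#' codon under the bias weights, with the planted start codon and a
#' complete or incomplete stop; RNAs and intergenic stretches i.i.d.
#' from the base frequencies), writes reverse-strand genes as reverse
#' complements, and assembles the circular sequence. In overlap regions
#' the downstream gene's bases win; planted per-gene start/stop codons
#' are then re-read from the assembled sequence, so the returned ground
#' truth is consistent with the emitted genome by construction.
#'
#' @param spec A [genomeSpec()] object.
#' @param seed Optional integer seed (deterministic output per seed).
#' @return A list: `genome` (an [AnnotatedMitogenome-class]) and `truth`,
#'   a list with `features`, `junction_gaps`, `spacer` totals
#'   (`n_spacers`, `total_spacer_bp`, `n_overlaps`, `total_overlap_bp`),
#'   `control_regions` (gaps >= `crMinLen`), `start_codons`,
#'   `stop_codons`, `base_freqs`, `seed`.
#' @export
generateGenome <- function(spec, seed = NULL) {
    stopifnot(inherits(spec, "GenomeSpec"))
    if (!is.null(seed)) set.seed(seed)
    inv <- spec$geneInventory
    gaps <- spec$junctionPlan
    n <- nrow(inv)
    start <- integer(n); end <- integer(n)
    start[1L] <- 1L
    for (i in seq_len(n)) {
        end[i] <- start[i] + inv$length[i] - 1L
        if (i < n) start[i + 1L] <- end[i] + gaps[i] + 1L
    }
    glen <- end[n] + gaps[n]
    if (glen < end[n]) stop("negative wrap gap not supported")

    weights <- spec$codonBias %||%
        .codonWeightsFromFreqs(spec$baseFreqs, spec$code)
    seq <- strsplit(generateSequenceWithComposition(glen, spec$baseFreqs),
                    "", fixed = TRUE)[[1L]]
    # AT-richer (or otherwise distinct) control-region composition
    if (!is.null(spec$crFreqs)) {
        gapStart <- end + 1L; gapLen <- gaps
        for (i in seq_len(n)) {
            if (gapLen[i] < spec$crMinLen) next
            idx <- (gapStart[i] + seq_len(gapLen[i]) - 2L) %% glen + 1L
            seq[idx] <- strsplit(generateSequenceWithComposition(
                gapLen[i], spec$crFreqs), "", fixed = TRUE)[[1L]]
        }
    }
    for (i in seq_len(n)) {
        s <- switch(inv$class[i],
            PCG = .simulateCDS(inv$length[i], inv$start_codon[i],
                               inv$stop_codon[i], weights, spec$code),
            generateSequenceWithComposition(inv$length[i], spec$baseFreqs))
        if (inv$strand[i] == "R") s <- .revComp(s)
        seq[start[i]:end[i]] <- strsplit(s, "", fixed = TRUE)[[1L]]
    }
    features <- data.frame(gene = inv$name, feature_class = inv$class,
                           strand = inv$strand, start = start, end = end,
                           wraps_origin = FALSE, partial = FALSE,
                           start_codon = NA_character_,
                           stop_codon = NA_character_,
                           stringsAsFactors = FALSE)
    genome <- annotatedMitogenome(features, genomeLength = glen,
                                  sequence = paste(seq, collapse = ""),
                                  circular = TRUE, label = spec$label)
    # realized start/stops, re-read from the assembled sequence
    ft <- geneFeatures(genome)
    pcgs <- ft$gene[ft$feature_class == "PCG"]
    cls <- lapply(pcgs, function(g)
        classifyStartStop(extractGeneSequence(genome, g), spec$code))
    ft$start_codon[match(pcgs, ft$gene)] <- vapply(cls, `[[`, "", "start")
    ft$stop_codon[match(pcgs, ft$gene)] <- vapply(cls, `[[`, "", "stop")
    genome@features <- ft

    inner <- gaps[-n]
    crIdx <- which(gaps >= spec$crMinLen)
    truth <- list(
        features = ft,
        junction_gaps = setNames(gaps, inv$name),
        n_spacers = sum(inner > 0L), total_spacer_bp = sum(inner[inner > 0L]),
        n_overlaps = sum(inner < 0L),
        total_overlap_bp = sum(abs(inner[inner < 0L])),
        control_regions = data.frame(
            after = inv$name[crIdx],
            length = gaps[crIdx],
            start = (end[crIdx]) %% glen + 1L,
            stringsAsFactors = FALSE),
        start_codons = setNames(vapply(cls, `[[`, "", "start"), pcgs),
        stop_codons = setNames(vapply(cls, `[[`, "", "stop"), pcgs),
        base_freqs = spec$baseFreqs, seed = seed)
    list(genome = genome, truth = truth)
}

#' Apply random rearrangement events to a gene order
#'
#' Applies `nTranspositions` single-gene moves (excise one gene, reinsert
#' it elsewhere with unchanged orientation) and `nInversions` block
#' inversions (reverse a contiguous block and flip its signs), in that
#' order, each drawn uniformly. The event log records every move and can
#' be replayed with [replayEvents()].
#'
#' @param order A [GeneOrder-class] with at least 3 genes.
#' @param nTranspositions,nInversions Non-negative event counts.
#' @param seed Optional integer seed.
#' @return A list: `order` (the rearranged [GeneOrder-class]) and
#'   `events` (list of `list(type, from, to)` / `list(type, i, j)`).
#' @export
permuteOrder <- function(order, nTranspositions = 0L, nInversions = 0L,
                         seed = NULL) {
    if (nTranspositions < 0L || nInversions < 0L)
        stop("event counts must be non-negative")
    n <- length(orderGenes(order))
    if (n < 3L) stop("order must have at least 3 genes")
    if (!is.null(seed)) set.seed(seed)
    events <- list()
    for (k in seq_len(nTranspositions)) {
        from <- sample.int(n, 1L)
        to <- sample(setdiff(seq_len(n), from), 1L)
        events[[length(events) + 1L]] <- list(type = "transposition",
                                              from = from, to = to)
    }
    for (k in seq_len(nInversions)) {
        i <- sample.int(n, 1L); j <- sample.int(n, 1L)
        events[[length(events) + 1L]] <- list(type = "inversion",
                                              i = min(i, j), j = max(i, j))
    }
    list(order = replayEvents(order, events), events = events)
}

#' @rdname permuteOrder
#' @param events An event log as produced by `permuteOrder()`.
#' @export
replayEvents <- function(order, events) {
    genes <- orderGenes(order); signs <- orderSigns(order)
    for (ev in events) {
        if (ev$type == "transposition") {
            g <- genes[ev$from]; s <- signs[ev$from]
            genes <- genes[-ev$from]; signs <- signs[-ev$from]
            at <- ev$to - 1L                # ev$to = final position
            genes <- append(genes, g, after = at)
            signs <- append(signs, s, after = at)
        } else if (ev$type == "inversion") {
            idx <- ev$i:ev$j
            genes[idx] <- rev(genes[idx])
            signs[idx] <- rev(ifelse(signs[idx] == "+", "-", "+"))
        } else stop("unknown event type '", ev$type, "'")
    }
    new("GeneOrder", genes = genes, orientation = signs,
        circular = order@circular, label = order@label)
}
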