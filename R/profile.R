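#' Aggregate analysis profile of one mitogenome
#'
#' Runs every analysis stage on one annotated mitogenome and collects the
#' results into a single machine-readable profile: identity block,
#' composition table, codon usage with RSCU, per-gene start/stop codons,
#' spacer/overlap summary, inferred control regions and the linearized
#' gene order. Coordinates-only genomes are first-class: blocks that need
#' a sequence are set to NULL and listed in `flags` instead of failing,
#' so a printed feature table alone drives the full structural analysis.
#'
#' @param genome An [AnnotatedMitogenome-class].
#' @param minCRLength Gap threshold for control-region inference, bp.
#' @param anchor Anchor gene for the linearized order (default "cox1");
#'   when absent the first gene is used.
#' @param code A [geneticCode()] list.
#' @return A [MitogenomeProfile-class] object.
#' @export
profileMitogenome <- function(genome, minCRLength = 500L, anchor = "cox1",
                              code = geneticCode()) {
    ft <- geneFeatures(genome)
    flags <- character()
    note <- function(blk, e) sprintf("%s: %s", blk, conditionMessage(e))
    grab <- function(blk, expr) tryCatch(expr, error = function(e) {
        flags <<- c(flags, note(blk, e)); NULL
    })
    cls <- table(factor(ft$feature_class, levels = VALID_CLASSES))
    identity <- list(label = genomeLabel(genome),
                     genome_length = genomeLength(genome),
                     circular = isCircular(genome),
                     has_sequence = hasSequence(genome),
                     n_genes = sum(ft$feature_class != "CR"),
                     n_pcg = unname(cls[["PCG"]]),
                     n_trna = unname(cls[["tRNA"]]),
                     n_rrna = unname(cls[["rRNA"]]),
                     class_lengths = as.list(featureClassLengths(genome)))
    composition <- grab("composition",
                        compositionTable(genome, minCRLength = minCRLength))
    codonUsage <- grab("codon_usage", countCodons(genome, code))
    startStop <- grab("start_stop", startStopTable(genome, code))
    spacers <- grab("spacers", spacerSummary(genome))
    crs <- grab("control_regions",
                inferControlRegions(genome, minLen = minCRLength))
    anch <- if (anchor %in% ft$gene) anchor else ft$gene[1L]
    geneOrd <- grab("gene_order",
                    linearizeOrder(genome, anchor = anch,
                                   minCRLength = minCRLength))
    new("MitogenomeProfile", identity = identity,
        composition = composition, codonUsage = codonUsage,
        startStop = startStop, spacers = spacers, controlRegions = crs,
        geneOrder = geneOrd, flags = flags)
}

.roundDF <- function(df, digits) {
    for (nm in names(df))
        if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
            df[[nm]] <- round(df[[nm]], digits[[nm]] %||% 6L)
    df
}

#' Serialize a mitogenome profile to JSON
#'
#' Stable, deterministic serialization: fixed block order, no wall-clock
#' fields. Rounding happens only here; defaults match descriptive-table
#' convention (percentages 2 d.p., skews 5 d.p., RSCU 3 d.p.).
#'
#' @param profile A [MitogenomeProfile-class] object.
#' @param file Optional output path; when NULL the JSON string is
#'   returned.
#' @param precision List with elements `pct`, `skew`, `rscu` controlling
#'   displayed decimals.
#' @return JSON string (invisibly when `file` is given).
#' @export
writeProfileJSON <- function(profile, file = NULL,
                             precision = list(pct = 2L, skew = 5L,
                                              rscu = 3L)) {
    comp <- profile@composition
    if (!is.null(comp)) {
        dig <- setNames(rep(precision$pct, ncol(comp)), names(comp))
        dig[c("at_skew", "gc_skew")] <- precision$skew
        comp <- .roundDF(comp, as.list(dig))
    }
    cu <- profile@codonUsage
    cuList <- if (is.null(cu)) NULL else list(
        table_id = cu@tableId,
        counts = as.list(codonCounts(cu)),
        family_counts = as.list(familyCounts(cu)),
        rscu = lapply(as.list(round(rscuValues(cu), precision$rscu)),
                      function(v) if (is.na(v)) NULL else v),
        stop_tally = as.list(stopTally(cu)))
    sp <- profile@spacers
    payload <- list(
        identity = profile@identity,
        composition = comp,
        codon_usage = cuList,
        start_stop = profile@startStop,
        spacers = sp,
        control_regions = profile@controlRegions,
        gene_order = if (is.null(profile@geneOrder)) NULL
                     else formatGeneOrder(profile@geneOrder),
        flags = as.list(profile@flags))
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            null = "null", na = "null", pretty = TRUE)
    if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
    txt
}
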