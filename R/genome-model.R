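#' @importFrom Biostrings DNAString reverseComplement
NULL

.asLines <- function(x) {
    if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
        return(readLines(x, warn = FALSE))
    if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
    x
}

.checkSequence <- function(seq) {
    seq <- toupper(seq)
    bad <- gsub("[ACGTN]", "", seq)
    if (nzchar(bad))
        stop("sequence contains ambiguity codes other than N: ",
             paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "))
    seq
}

.revComp <- function(seq) {
    as.character(reverseComplement(DNAString(seq)))
}

#' Construct a gene feature record
#'
#' One annotated gene: name, class, strand and 1-based inclusive
#' coordinates. Returned as a one-row `data.frame` so features can be
#' rbind-ed into the table an [AnnotatedMitogenome-class] carries.
#'
#' @param gene Gene identifier (e.g. "cox1", "trnS2-tca").
#' @param feature_class One of "PCG", "tRNA", "rRNA", "CR".
#' @param strand "F" (deposited strand) or "R" (reverse complement).
#' @param start,end 1-based inclusive coordinates.
#' @param wraps_origin Whether the feature crosses the circular origin.
#' @param partial Whether a boundary was annotated as partial ("<"/">").
#' @param start_codon,stop_codon Optional annotated codons (PCGs).
#' @return A one-row `data.frame`.
#' @export
geneFeature <- function(gene, feature_class, strand, start, end,
                        wraps_origin = FALSE, partial = FALSE,
                        start_codon = NA_character_,
                        stop_codon = NA_character_) {
    data.frame(gene = gene, feature_class = feature_class, strand = strand,
               start = as.integer(start), end = as.integer(end),
               wraps_origin = wraps_origin, partial = partial,
               start_codon = start_codon, stop_codon = stop_codon,
               stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' @param features A `data.frame` of features (see [geneFeature()]); missing
#'   optional columns are filled with defaults. Features are sorted by
#'   `start` (stable).
#' @param genomeLength Total length in bp; defaults to `max(end)` when a
#'   sequence is absent, `nchar(sequence)` otherwise.
#' @param sequence Optional nucleotide string over A,C,G,T,N.
#' @param circular Logical, default TRUE.
#' @param label Identifier used in reports.
#' @return An [AnnotatedMitogenome-class] object.
#' @examples
#' g <- annotatedMitogenome(
#'   rbind(geneFeature("gA", "PCG", "F", 1, 9),
#'         geneFeature("gB", "tRNA", "R", 15, 80)),
#'   genomeLength = 100)
#' featureLengths(g)
#' @export
annotatedMitogenome <- function(features, genomeLength = NULL,
                                sequence = NA_character_, circular = TRUE,
                                label = "mitogenome") {
    if (is.null(features) || nrow(features) == 0L)
        stop("no features: an annotated mitogenome needs at least one gene")
    defaults <- list(wraps_origin = FALSE, partial = FALSE,
                     start_codon = NA_character_, stop_codon = NA_character_)
    for (nm in names(defaults))
        if (is.null(features[[nm]])) features[[nm]] <- defaults[[nm]]
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    if (!is.na(sequence)) sequence <- .checkSequence(sequence)
    if (is.null(genomeLength))
        genomeLength <- if (!is.na(sequence)) nchar(sequence)
                        else max(features$end)
    new("AnnotatedMitogenome", sequence = sequence,
        genomeLength = as.integer(genomeLength), circular = circular,
        features = features, label = label)
}

#' Construct a signed gene order
#'
#' @param genes Character vector of gene names, or a single string of
#'   whitespace-separated signed names ("-" prefix = reverse orientation).
#' @param orientation Optional "+"/"-" vector matching `genes`.
#' @param circular Logical, default TRUE.
#' @param label Identifier.
#' @return A [GeneOrder-class] object.
#' @export
geneOrder <- function(genes, orientation = NULL, circular = TRUE,
                      label = "order") {
    if (length(genes) == 1L && grepl("\\s", trimws(genes)))
        genes <- strsplit(trimws(genes), "\\s+")[[1L]]
    if (is.null(orientation)) {
        orientation <- ifelse(startsWith(genes, "-"), "-", "+")
        genes <- sub("^-", "", genes)
    }
    new("GeneOrder", genes = genes, orientation = orientation,
        circular = circular, label = label)
}

# ---- GenBank flat file ------------------------------------------------------

.parseLocation <- function(loc, line) {
    raw <- loc
    wraps <- FALSE
    strand <- "F"
    partial <- grepl("[<>]", loc)
    loc <- gsub("[<>]", "", loc)
    if (grepl("^complement\\(", loc)) {
        strand <- "R"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
        loc <- sub("^join\\((.*)\\)$", "\\1", loc)
        parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
        if (length(parts) != 2L)
            stop("cannot parse location '", raw, "' at line: ", line)
        wraps <- TRUE
        a <- strsplit(parts[1L], "..", fixed = TRUE)[[1L]]
        b <- strsplit(parts[2L], "..", fixed = TRUE)[[1L]]
        se <- c(a[1L], b[length(b)])
    } else {
        se <- strsplit(loc, "..", fixed = TRUE)[[1L]]
        if (length(se) == 1L) se <- c(se, se)
    }
    se <- suppressWarnings(as.integer(se))
    if (anyNA(se))
        stop("cannot parse location '", raw, "' at line: ", line)
    list(start = se[1L], end = se[2L], strand = strand, wraps = wraps,
         partial = partial)
}

#' Parse a GenBank flat file into an annotated mitogenome
#'
#' Reads LOCUS (genome length, circular flag), the FEATURES table (CDS,
#' tRNA, rRNA, D-loop and misc_feature records; `complement(...)` maps to
#' strand R, a two-segment `join(...)` to an origin-wrapping feature) and
#' the ORIGIN sequence block. CDS features become class PCG, D-loop and
#' misc_feature become CR. Plain `gene` and `source` records are skipped to
#' avoid duplicating their CDS/tRNA/rRNA counterparts.
#'
#' @param x File path or GenBank record text.
#' @param label Genome label; defaults to the LOCUS name.
#' @return An [AnnotatedMitogenome-class] object; coordinates-only (with a
#'   warning) when the record has no ORIGIN block.
#' @export
parseGenBank <- function(x, label = NULL) {
    lines <- .asLines(x)
    locus <- grep("^LOCUS", lines, value = TRUE)
    if (!length(locus)) stop("not a GenBank record: no LOCUS line")
    toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
    glen <- as.integer(toks[which(toks == "bp") - 1L][1L])
    if (is.na(glen)) stop("cannot read genome length from LOCUS line")
    circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))
    if (is.null(label)) label <- toks[2L]

    fstart <- grep("^FEATURES", lines)
    if (!length(fstart)) stop("not a GenBank record: no FEATURES block")
    ostart <- grep("^ORIGIN", lines)
    fend <- if (length(ostart)) ostart[1L] - 1L else length(lines)
    flines <- lines[(fstart[1L] + 1L):fend]

    keymap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                `D-loop` = "CR", misc_feature = "CR")
    feats <- list(); cur <- NULL
    flush <- function(cur) {
        if (is.null(cur)) return(NULL)
        nm <- cur$gene %||% cur$product %||%
              paste0(cur$key, "_", length(feats) + 1L)
        loc <- .parseLocation(cur$loc, cur$line)
        geneFeature(nm, keymap[[cur$key]], loc$strand, loc$start, loc$end,
                    wraps_origin = loc$wraps, partial = loc$partial)
    }
    for (ln in flines) {
        if (grepl("^ {5}\\S", ln)) {            # new feature key
            toks <- strsplit(trimws(ln), "\\s+")[[1L]]
            key <- toks[1L]
            f <- flush(cur); if (!is.null(f)) feats[[length(feats) + 1L]] <- f
            cur <- if (key %in% names(keymap))
                list(key = key, loc = paste(toks[-1L], collapse = ""),
                     line = ln)
            else NULL
        } else if (!is.null(cur)) {
            q <- trimws(ln)
            if (grepl('^/gene="?', q))
                cur$gene <- gsub('^/gene="?|"$', "", q)
            else if (grepl('^/product="?', q))
                cur$product <- gsub('^/product="?|"$', "", q)
            else if (!startsWith(q, "/"))       # continuation of location
                cur$loc <- paste0(cur$loc, q)
        }
    }
    f <- flush(cur); if (!is.null(f)) feats[[length(feats) + 1L]] <- f
    if (!length(feats)) stop("no gene features found in FEATURES block")
    features <- do.call(rbind, feats)

    seq <- NA_character_
    if (length(ostart)) {
        send <- grep("^//", lines)
        send <- if (length(send)) send[1L] - 1L else length(lines)
        sl <- lines[(ostart[1L] + 1L):send]
        seq <- .checkSequence(gsub("[0-9 ]", "", paste(sl, collapse = "")))
    } else {
        warning("record has no ORIGIN block; returning coordinates-only genome")
    }
    annotatedMitogenome(features, genomeLength = glen, sequence = seq,
                        circular = circular, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- feature-table TSV ------------------------------------------------------

#' Read / write the tab-separated feature-table dialect
#'
#' The dialect is one optional header line
#' `#genome_length=<int> circular=<true|false>`, an optional column-name
#' line, then tab-separated columns `gene strand start end class` with
#' optional `start_codon stop_codon`. A leading `<` or `>` on a coordinate
#' marks a partial boundary: it is stripped and recorded in the `partial`
#' flag, the printed coordinate is used verbatim. Without the header line
#' the genome length defaults to `max(end)`. The resulting genome is in
#' coordinates-only mode; attach a sequence via the `sequence` argument.
#'
#' @param x File path or TSV text.
#' @param sequence Optional nucleotide sequence to attach.
#' @param label Genome label.
#' @return An [AnnotatedMitogenome-class] object.
#' @examples
#' tsv <- paste("#genome_length=100 circular=true",
#'              "gA\tF\t1\t30\tPCG", "gB\tR\t41\t90\trRNA", sep = "\n")
#' g <- parseFeatureTable(tsv)
#' geneFeatures(g)
#' @export
parseFeatureTable <- function(x, sequence = NA_character_,
                              label = "mitogenome") {
    lines <- .asLines(x)
    glen <- NULL; circular <- TRUE
    hdr <- grep("^#", lines, value = TRUE)
    if (length(hdr)) {
        m <- regmatches(hdr[1L], regexec("genome_length=([0-9]+)", hdr[1L]))[[1L]]
        if (length(m) == 2L) glen <- as.integer(m[2L])
        if (grepl("circular=false", hdr[1L], fixed = TRUE)) circular <- FALSE
    }
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    lines <- lines[!grepl("^gene\\t", lines)]   # optional column-name line
    if (!length(lines)) stop("no features in feature table")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(cells)
    if (any(ncol < 5L))
        stop("feature table rows need at least 5 columns ",
             "(gene, strand, start, end, class)")
    getcol <- function(i) vapply(cells, function(r)
        if (length(r) >= i) trimws(r[i]) else NA_character_, character(1L))
    gene <- getcol(1L); strand <- getcol(2L)
    rawstart <- getcol(3L); rawend <- getcol(4L); cls <- getcol(5L)
    startc <- getcol(6L); stopc <- getcol(7L)
    startc[startc %in% c("", "-")] <- NA_character_
    stopc[stopc %in% c("", "-")] <- NA_character_
    partial <- grepl("[<>]", rawstart) | grepl("[<>]", rawend)
    start <- as.integer(gsub("[<>, ]", "", rawstart))
    end <- as.integer(gsub("[<>, ]", "", rawend))
    if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in table")
    if (anyDuplicated(gene))
        stop("duplicate gene names: ",
             paste(unique(gene[duplicated(gene)]), collapse = ", "))
    if (any(start > end))
        stop("start > end for ", paste(gene[start > end], collapse = ", "),
             " (wrap-around rows are not expressible in the table dialect)")
    features <- data.frame(gene = gene, feature_class = cls, strand = strand,
                           start = start, end = end, wraps_origin = FALSE,
                           partial = partial, start_codon = startc,
                           stop_codon = stopc, stringsAsFactors = FALSE)
    annotatedMitogenome(features, genomeLength = glen, sequence = sequence,
                        circular = circular, label = label)
}

#' @rdname parseFeatureTable
#' @param genome An [AnnotatedMitogenome-class] object.
#' @param file Optional path; when NULL the TSV text is returned.
#' @export
writeFeatureTable <- function(genome, file = NULL) {
    ft <- geneFeatures(genome)
    if (!nrow(ft)) stop("no features to write")
    hdr <- sprintf("#genome_length=%d circular=%s", genomeLength(genome),
                   if (isCircular(genome)) "true" else "false")
    start <- ifelse(ft$partial, paste0("<", ft$start), as.character(ft$start))
    codon <- function(x) ifelse(is.na(x), "-", x)
    rows <- paste(ft$gene, ft$strand, start, ft$end, ft$feature_class,
                  codon(ft$start_codon), codon(ft$stop_codon), sep = "\t")
    txt <- paste(c(hdr, rows), collapse = "\n")
    if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
    txt
}

# ---- FASTA ------------------------------------------------------------------

#' Read / write a single-record FASTA file
#'
#' Thin wrappers over Biostrings with the package's sequence-alphabet check
#' (only A,C,G,T,N allowed).
#'
#' @param file Path to a FASTA file.
#' @return `readFASTA`: a named character scalar (the sequence).
#' @export
readFASTA <- function(file) {
    set <- Biostrings::readDNAStringSet(file)
    if (length(set) != 1L)
        stop("expected exactly one FASTA record, found ", length(set))
    setNames(.checkSequence(as.character(set[[1L]])), names(set)[1L])
}

#' @rdname readFASTA
#' @param seq Nucleotide string.
#' @param name Record name.
#' @export
writeFASTA <- function(seq, file, name = "sequence") {
    set <- Biostrings::DNAStringSet(setNames(as.character(seq), name))
    Biostrings::writeXStringSet(set, file, width = 70L)
    invisible(file)
}

# ---- gene-order text --------------------------------------------------------

#' Gene-order text format
#'
#' A gene order serializes to whitespace-separated signed names: a "-"
#' prefix marks reverse orientation ("cox1 trnR-cga ... -nad6 ...").
#'
#' @param order A [GeneOrder-class] object.
#' @return `formatGeneOrder`: a single string.
#' @export
formatGeneOrder <- function(order) {
    paste(ifelse(orderSigns(order) == "-", paste0("-", orderGenes(order)),
                 orderGenes(order)), collapse = " ")
}

#' @rdname formatGeneOrder
#' @param file Output path (writeGeneOrder) or input path/text (readGeneOrder).
#' @export
writeGeneOrder <- function(order, file = NULL) {
    txt <- formatGeneOrder(order)
    if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
    txt
}

#' @rdname formatGeneOrder
#' @param x File path or order text.
#' @param circular,label Passed to [geneOrder()].
#' @export
readGeneOrder <- function(x, circular = TRUE, label = "order") {
    lines <- .asLines(x)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    if (!length(lines)) stop("empty gene-order input")
    geneOrder(paste(lines, collapse = " "), circular = circular,
              label = label)
}

# ---- sequence extraction ----------------------------------------------------

#' Extract the coding-strand sequence of one gene
#'
#' Returns the sense (coding-strand) sequence: the genomic slice
#' `[start..end]` for strand F, its reverse complement for strand R.
#' Origin-wrapping features concatenate the tail and head of the genome
#' before strand handling.
#'
#' @param genome A sequence-bearing [AnnotatedMitogenome-class].
#' @param name Gene identifier.
#' @return Nucleotide string.
#' @examples
#' g <- annotatedMitogenome(geneFeature("gA", "PCG", "R", 1, 4),
#'                          sequence = "ATGCAAAAAA")
#' extractGeneSequence(g, "gA")  # "GCAT"
#' @export
extractGeneSequence <- function(genome, name) {
    if (!hasSequence(genome))
        stop("genome is coordinates-only: no sequence to extract from")
    ft <- geneFeatures(genome)
    i <- match(name, ft$gene)
    if (is.na(i))
        stop("unknown gene '", name, "'; available: ",
             paste(ft$gene, collapse = ", "))
    seq <- genomeSequence(genome)
    s <- if (ft$wraps_origin[i])
        paste0(substring(seq, ft$start[i], genomeLength(genome)),
               substring(seq, 1L, ft$end[i]))
    else substring(seq, ft$start[i], ft$end[i])
    if (ft$strand[i] == "R") .revComp(s) else s
}
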