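#' Linearize a circular gene order at an anchor gene
#'
#' Rotates the circular gene order of an annotated genome (or an existing
#' [GeneOrder-class]) so that the anchor gene — cox1 by field convention —
#' comes first with + orientation. When the anchor lies on the reverse
#' strand the whole order is flipped (reversed with all signs inverted,
#' the circular mirror image) before rotation, so comparisons between
#' genomes deposited on opposite strands are well defined.
#'
#' @param x An [AnnotatedMitogenome-class] or [GeneOrder-class].
#' @param anchor Anchor gene name (default "cox1").
#' @param includeCR Include control-region features as pseudo-genes
#'   (default TRUE); for genomes without annotated CR features they are
#'   inferred from gaps `>= minCRLength`.
#' @param minCRLength Gap threshold for CR inference, bp.
#' @return A [GeneOrder-class] starting at `anchor` with "+" orientation.
#' @examples
#' o <- geneOrder("b c a")
#' formatGeneOrder(linearizeOrder(o, anchor = "a"))  # "a b c"
#' @export
linearizeOrder <- function(x, anchor = "cox1", includeCR = TRUE,
                           minCRLength = 500L) {
    if (is(x, "AnnotatedMitogenome")) {
        if (includeCR && !any(geneFeatures(x)$feature_class == "CR"))
            x <- addInferredControlRegions(x, minLen = minCRLength)
        ft <- geneFeatures(x)
        if (!includeCR) ft <- ft[ft$feature_class != "CR", , drop = FALSE]
        ord <- new("GeneOrder", genes = ft$gene,
                   orientation = ifelse(ft$strand == "R", "-", "+"),
                   circular = isCircular(x), label = genomeLabel(x))
    } else ord <- x
    i <- match(anchor, ord@genes)
    if (is.na(i))
        stop("anchor gene '", anchor, "' absent from order")
    genes <- ord@genes; signs <- ord@orientation
    if (signs[i] == "-") {
        genes <- rev(genes)
        signs <- rev(ifelse(signs == "-", "+", "-"))
        i <- match(anchor, genes)
    }
    rot <- if (i == 1L) seq_along(genes)
           else c(i:length(genes), seq_len(i - 1L))
    new("GeneOrder", genes = genes[rot], orientation = signs[rot],
        circular = ord@circular, label = ord@label)
}

# canonical form of an oriented adjacency: (x,sx)->(y,sy) == (-y)->( -x)
.adjacencies <- function(genes, signs) {
    n <- length(genes)
    if (n < 2L) return(character())
    flip <- function(s) ifelse(s == "+", "-", "+")
    fwd <- paste0(signs[-n], genes[-n], ">", signs[-1L], genes[-1L])
    rev_ <- paste0(flip(signs[-1L]), genes[-1L], ">",
                   flip(signs[-n]), genes[-n])
    pmin(fwd, rev_)
}

#' Compare two signed gene orders
#'
#' Restricts both orders to their shared gene set (order and orientation
#' preserved; private genes are reported, not compared), forms the
#' oriented adjacency sets — an adjacency x→y counts as equal to
#' (−y)→(−x) — and counts breakpoints: adjacencies of one order missing
#' from the other. Both restricted orders have the same number of
#' adjacencies, so the breakpoint count is symmetric.
#'
#' @param a,b [GeneOrder-class] objects (normally both produced by
#'   [linearizeOrder()] with the same anchor).
#' @return A list: `shared_adjacencies` (canonical strings),
#'   `n_breakpoints`, `strand_flips` (genes with opposite orientation),
#'   `gene_set_diff` (list `only_a`, `only_b`), `n_shared_genes`.
#' @examples
#' a <- geneOrder("a b c d"); b <- geneOrder("a c b d")
#' compareOrders(a, b)$n_breakpoints  # 3
#' @export
compareOrders <- function(a, b) {
    shared <- intersect(orderGenes(a), orderGenes(b))
    if (!length(shared))
        stop("orders share no genes; nothing to compare")
    restrict <- function(o) {
        keep <- orderGenes(o) %in% shared
        list(genes = orderGenes(o)[keep], signs = orderSigns(o)[keep])
    }
    ra <- restrict(a); rb <- restrict(b)
    adjA <- .adjacencies(ra$genes, ra$signs)
    adjB <- .adjacencies(rb$genes, rb$signs)
    sharedAdj <- intersect(adjA, adjB)
    sa <- setNames(ra$signs, ra$genes); sb <- setNames(rb$signs, rb$genes)
    flips <- shared[sa[shared] != sb[shared]]
    list(shared_adjacencies = sharedAdj,
         n_breakpoints = length(adjA) - length(sharedAdj),
         strand_flips = flips,
         gene_set_diff = list(only_a = setdiff(orderGenes(a), shared),
                              only_b = setdiff(orderGenes(b), shared)),
         n_shared_genes = length(shared))
}

#' Pairwise breakpoint-distance matrix
#'
#' @param orders A list of two or more [GeneOrder-class] objects; names or
#'   labels become dimnames.
#' @return Symmetric integer matrix of breakpoint counts, zero diagonal.
#' @export
compareMatrix <- function(orders) {
    if (length(orders) < 2L) stop("need at least two gene orders")
    labs <- names(orders)
    if (is.null(labs))
        labs <- vapply(orders, function(o) o@label, character(1L))
    if (anyDuplicated(labs)) labs <- make.unique(labs)
    n <- length(orders)
    m <- matrix(0L, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        m[i, j] <- m[j, i] <-
            compareOrders(orders[[i]], orders[[j]])$n_breakpoints
    m
}
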