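test_that("sequence generation is deterministic per seed and honours degenerate freqs", {
    f <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    expect_identical(generateSequenceWithComposition(500, f, seed = 5),
                     generateSequenceWithComposition(500, f, seed = 5))
    expect_false(identical(generateSequenceWithComposition(500, f, seed = 5),
                           generateSequenceWithComposition(500, f, seed = 6)))
    expect_equal(generateSequenceWithComposition(
        8, c(A = 1, C = 0, G = 0, T = 0)), strrep("A", 8))
})

test_that("a two-gene spec realizes the planned junctions", {
    inv <- data.frame(name = c("a", "b"), class = c("PCG", "tRNA"),
                      strand = "F", length = c(90L, 70L))
    sim <- generateGenome(genomeSpec(inv, c(5L, 12L)), seed = 1)
    jn <- junctions(sim$genome)
    expect_equal(jn$gap, c(5L, 12L))
    expect_equal(jn$wrap, c(FALSE, TRUE))
    expect_equal(genomeLength(sim$genome), 90L + 70L + 5L + 12L)
})

test_that("genome generation is deterministic and validates its spec", {
    spec <- benthodytesGenomeSpec()
    a <- generateGenome(spec, seed = 8); b <- generateGenome(spec, seed = 8)
    expect_identical(genomeSequence(a$genome), genomeSequence(b$genome))
    expect_identical(a$truth, b$truth)
    inv <- data.frame(name = c("a", "b"), class = c("PCG", "tRNA"),
                      strand = "F", length = c(90L, 70L))
    # overlap at least as long as the next gene is infeasible
    expect_error(genomeSpec(inv, c(-70L, 2L)), "infeasible")
    expect_error(genomeSpec(inv[integer(0), ], integer(0)))
})

test_that("planted structural layout is recovered exactly by the analyses", {
    sim <- generateGenome(benthodytesGenomeSpec(), seed = 13)
    g <- sim$genome; tr <- sim$truth
    s <- spacerSummary(g)
    expect_equal(s$n_spacers, tr$n_spacers)
    expect_equal(s$total_spacer_bp, tr$total_spacer_bp)
    expect_equal(s$n_overlaps, tr$n_overlaps)
    expect_equal(s$total_overlap_bp, tr$total_overlap_bp)
    cr <- inferControlRegions(g)
    expect_equal(cr$length, tr$control_regions$length)
    expect_equal(cr$after, tr$control_regions$after)
    jn <- junctions(g)
    expect_equal(jn$gap, unname(tr$junction_gaps[jn$upstream]))
    ss <- startStopTable(g)
    expect_equal(setNames(ss$start_codon, ss$gene), tr$start_codons)
    expect_equal(setNames(ss$stop_codon, ss$gene), tr$stop_codons)
})

test_that("planted start and incomplete stop codons appear unless overwritten", {
    # overlap-free layout: planted codons survive assembly verbatim
    inv <- data.frame(name = c("p0", "p1", "p2", "t1"),
                      class = c("PCG", "PCG", "PCG", "tRNA"),
                      strand = c("F", "R", "F", "F"),
                      length = c(90L, 91L, 92L, 65L),
                      start_codon = c("ATG", "ATT", "ATG", NA),
                      stop_codon = c("TAG", NA, NA, NA))
    sim <- generateGenome(genomeSpec(inv, c(3L, 4L, 5L, 6L)), seed = 4)
    ss <- startStopTable(sim$genome)
    expect_equal(setNames(ss$start_codon, ss$gene),
                 c(p0 = "ATG", p1 = "ATT", p2 = "ATG"))
    # stops: 90 %% 3 == 0 -> planted TAG; 91 -> "T"; 92 -> "TA"
    expect_equal(setNames(ss$stop_codon, ss$gene),
                 c(p0 = "TAG", p1 = "T", p2 = "TA"))
})

test_that("generated composition tracks the request at genome scale", {
    sim <- generateGenome(benthodytesGenomeSpec(), seed = 19)
    cs <- baseComposition(genomeSequence(sim$genome))
    expect_lt(abs(cs$pct_AT - 67.86), 2)
})

test_that("concentrating a family's codon mass drives its RSCU to the family size", {
    code <- geneticCode()
    fam <- codonFamilies(code)
    bias <- setNames(rep(1, length(fam)), names(fam))
    bias[names(fam)[fam == "Pro"]] <- 0
    bias["CCT"] <- 1    # all Pro mass on CCT
    inv <- data.frame(name = "big", class = "PCG", strand = "F",
                      length = 9000L)
    sim <- generateGenome(genomeSpec(inv, 50L, codonBias = bias,
                                     label = "biased"), seed = 23)
    r <- rscuValues(countCodons(sim$genome, code))
    expect_lt(abs(r[["CCT"]] - 4), 0.2)
})

test_that("permutation events replay exactly and identity means no events", {
    base <- geneOrder("a b c d")
    id <- permuteOrder(base, 0L, 0L, seed = 1)
    expect_equal(orderGenes(id$order), orderGenes(base))
    expect_equal(id$events, list())
    # explicit event: move c (position 3) to final position 2
    moved <- replayEvents(base, list(list(type = "transposition",
                                          from = 3L, to = 2L)))
    expect_equal(orderGenes(moved), c("a", "c", "b", "d"))
    rnd <- permuteOrder(linearizeOrder(fixtureGenome()), 3L, 2L, seed = 77)
    expect_equal(orderGenes(replayEvents(linearizeOrder(fixtureGenome()),
                                         rnd$events)),
                 orderGenes(rnd$order))
    expect_error(permuteOrder(base, -1L), "non-negative")
})

test_that("inversions flip block orientation and order", {
    base <- geneOrder("a b c d")
    inv <- replayEvents(base, list(list(type = "inversion", i = 2L, j = 3L)))
    expect_equal(orderGenes(inv), c("a", "c", "b", "d"))
    expect_equal(orderSigns(inv), c("+", "-", "-", "+"))
})
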