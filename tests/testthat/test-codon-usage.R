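test_that("translation table 9 has the echinoderm reassignments", {
    code <- geneticCode()
    expect_equal(unname(code$codonToAA[c("AGA", "AGG")]), c("S", "S"))
    expect_equal(unname(code$codonToAA["ATA"]), "I")
    expect_equal(unname(code$codonToAA["AAA"]), "N")
    expect_equal(unname(code$codonToAA["TGA"]), "W")
    expect_setequal(code$stopCodons, c("TAA", "TAG"))
    expect_equal(length(code$codonToAA), 64L)
})

test_that("synonymous families split Leu and Ser as plotted in usage figures", {
    fam <- codonFamilies()
    expect_equal(length(fam), 62L)   # 64 - 2 stops under table 9
    expect_setequal(names(fam)[fam == "Ser-AGN"],
                    c("AGT", "AGC", "AGA", "AGG"))
    expect_setequal(names(fam)[fam == "Leu-UUR"], c("TTA", "TTG"))
    expect_setequal(names(fam)[fam == "Leu-CUN"],
                    c("CTT", "CTC", "CTA", "CTG"))
    merged <- codonFamilies(merged = TRUE)
    expect_equal(sum(merged == "Leu"), 6L)
    expect_equal(sum(merged == "Ser"), 8L)
})

test_that("splitCodons arithmetic: triplets from position 1 plus mod-3 tail", {
    sc <- splitCodons("ATGTAA")
    expect_equal(sc$codons, c("ATG", "TAA"))
    expect_equal(sc$tail, "")
    sc7 <- splitCodons(randomSeq(7))
    expect_equal(length(sc7$codons), 2L)
    expect_equal(nchar(sc7$tail), 1L)
    # a 688-nt CDS (cox2-sized) yields 229 triplets and a 1-base tail
    sc688 <- splitCodons(randomSeq(688))
    expect_equal(length(sc688$codons), 229L)
    expect_equal(nchar(sc688$tail), 1L)
    expect_error(splitCodons("AT"), "shorter")
})

test_that("start/stop classification covers complete, incomplete and anomalous ends", {
    expect_equal(classifyStartStop("ATGAAATAA")[c("start", "stop")],
                 list(start = "ATG", stop = "TAA"))
    expect_equal(classifyStartStop("ATTAAATAG")$stop, "TAG")
    t1 <- classifyStartStop("ATGAAAT")
    expect_equal(t1$stop, "T"); expect_false(t1$anomalous)
    t2 <- classifyStartStop("ATGAAATA")
    expect_equal(t2$stop, "TA")
    an <- classifyStartStop("ATGAAAAAA")
    expect_true(an$anomalous)
})

test_that("codon counting pools genes and keeps stops in a separate tally", {
    g <- annotatedMitogenome(geneFeature("gA", "PCG", "F", 1, 9),
                             sequence = "ATGATTTAA")
    cu <- countCodons(g)
    cnt <- codonCounts(cu)
    expect_equal(unname(cnt[c("ATG", "ATT")]), c(1L, 1L))
    expect_equal(sum(cnt), 2L)
    expect_equal(unname(stopTally(cu)["TAA"]), 1L)
    # ATG -> Met, ATT -> Ile under table 9
    expect_equal(unname(familyCounts(cu)[c("Met", "Ile")]), c(1L, 1L))
})

test_that("RSCU follows the definition: count x family size / family total", {
    g <- annotatedMitogenome(geneFeature("gA", "PCG", "F", 1, 18),
                             sequence = paste0("ATG", strrep("CCT", 4), "TAA"))
    cu <- countCodons(g)
    r <- rscuValues(cu)
    # Pro family (CCN): all 4 counts on CCT -> RSCU 4, siblings 0
    expect_equal(unname(r["CCT"]), 4)
    expect_equal(unname(r[c("CCC", "CCA", "CCG")]), c(0, 0, 0))
    # families never observed are flagged null
    expect_true(is.na(r["GGG"]))
    # uniform usage within a family gives RSCU 1 everywhere
    g2 <- annotatedMitogenome(geneFeature("gA", "PCG", "F", 1, 18),
                              sequence = paste0("ATG", "GGA", "GGC",
                                                "GGG", "GGT", "TAA"))
    r2 <- rscuValues(countCodons(g2))
    expect_equal(unname(r2[c("GGA", "GGC", "GGG", "GGT")]), rep(1, 4))
})

test_that("RSCU sums over each observed family equal the family size", {
    fam <- codonFamilies()
    set.seed(31)
    for (i in 1:20) {
        counts <- setNames(rpois(length(fam), lambda = sample(1:20, 1)),
                           names(fam))
        tab <- new("CodonUsageTable", counts = as.integer(counts) |>
                       setNames(names(fam)),
                   familyOf = fam,
                   aaCounts = tapply(counts, fam, sum) |> as.integer() |>
                       setNames(sort(unique(fam))),
                   rscu = numeric(), stopTally = integer(),
                   perGeneStart = character(), perGeneStop = character(),
                   tableId = 9L, mergedFamilies = FALSE)
        r <- computeRSCU(tab)
        sums <- tapply(r, fam[names(r)], sum)
        sizes <- table(fam)[names(sums)]
        obs <- tapply(counts, fam[names(counts)], sum)[names(sums)] > 0
        expect_equal(as.numeric(sums[obs]), as.numeric(sizes[obs]))
    }
})

test_that("codon bookkeeping: counted + stop triplets = all complete triplets", {
    sim <- generateGenome(benthodytesGenomeSpec(), seed = 17)
    g <- sim$genome
    cu <- countCodons(g)
    lens <- featureLengths(g)[geneFeatures(g)$feature_class == "PCG"]
    totalTriplets <- sum(lens %/% 3L)
    completeStops <- sum(stopTally(cu)[c("TAA", "TAG")])
    expect_equal(sum(codonCounts(cu)) + completeStops, totalTriplets)
    # incomplete tails tallied once per mod-3 gene
    expect_equal(sum(stopTally(cu)[c("T", "TA")]), sum(lens %% 3L > 0))
})

test_that("simulated PCGs translate without internal terminators", {
    inv <- data.frame(name = c("p1", "p2", "t1"),
                      class = c("PCG", "PCG", "tRNA"),
                      strand = c("F", "R", "F"),
                      length = c(300L, 450L, 70L))
    sim <- generateGenome(genomeSpec(inv, c(5L, 3L, 10L)), seed = 9)
    code <- geneticCode()
    for (gname in c("p1", "p2")) {
        aa <- translateCDS(extractGeneSequence(sim$genome, gname), code)
        internal <- substring(aa, 1, nchar(aa) - 1L)
        expect_false(grepl("*", internal, fixed = TRUE))
    }
})

test_that("start/stop table uses annotation in coordinates-only mode", {
    g <- fixtureGenome()
    ss <- startStopTable(g)
    expect_equal(nrow(ss), 13L)
    expect_equal(unique(ss$source), "annotation")
    expect_equal(ss$start_codon[ss$gene == "nad4l"], "ATT")
    expect_equal(ss$stop_codon[ss$gene == "cox1"], "TAG")
    expect_setequal(ss$gene[ss$stop_codon == "T"],
                    c("cox2", "nad4", "cytb"))
})
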