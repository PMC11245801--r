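test_that("a minimal GenBank record parses into one PCG feature", {
    g <- parseGenBank(genbankRecord())
    expect_s4_class(g, "AnnotatedMitogenome")
    expect_equal(genomeLength(g), 20L)
    expect_true(isCircular(g))
    ft <- geneFeatures(g)
    expect_equal(nrow(ft), 1L)
    expect_equal(ft$gene, "cox1")
    expect_equal(ft$feature_class, "PCG")
    expect_equal(c(ft$start, ft$end), c(1L, 9L))
    expect_equal(genomeSequence(g), "ATGGCCAAATGAACGTACGT")
})

test_that("GenBank complement() maps to strand R and tRNA/rRNA classes stick", {
    g <- parseGenBank(genbankRecord(features = c(
        "     CDS             complement(3..11)",
        '                     /gene="nad6"',
        "     tRNA            13..18",
        '                     /gene="trnW-tga"')))
    ft <- geneFeatures(g)
    expect_equal(ft$strand[ft$gene == "nad6"], "R")
    expect_equal(ft$feature_class[ft$gene == "trnW-tga"], "tRNA")
    expect_equal(unname(featureLengths(g)["nad6"]), 9L)
})

test_that("GenBank without ORIGIN downgrades to coordinates-only with warning", {
    expect_warning(g <- parseGenBank(genbankRecord(origin = FALSE)),
                   "coordinates-only")
    expect_false(hasSequence(g))
    expect_equal(genomeLength(g), 20L)
})

test_that("malformed GenBank locations raise an error naming the line", {
    expect_error(parseGenBank(genbankRecord(features = c(
        "     CDS             oops..9",
        '                     /gene="bad"'))), "cannot parse location")
})

test_that("the shipped 37-gene annotation parses with the printed geometry", {
    g <- fixtureGenome()
    ft <- geneFeatures(g)
    expect_equal(nrow(ft), 37L)
    expect_equal(sum(ft$feature_class == "PCG"), 13L)
    expect_equal(sum(ft$feature_class == "tRNA"), 22L)
    expect_equal(sum(ft$feature_class == "rRNA"), 2L)
    expect_equal(genomeLength(g), 17386L)
    expect_false(hasSequence(g))
    # spot checks against printed rows
    expect_equal(unname(featureLengths(g)["atp6"]), 684L)
    expect_equal(unname(featureLengths(g)["nad6"]), 489L)
    expect_equal(ft$strand[ft$gene == "nad6"], "R")
    # partial-boundary marker on nad4l is recorded, coordinates verbatim
    expect_true(ft$partial[ft$gene == "nad4l"])
    expect_equal(ft$start[ft$gene == "nad4l"], 1626L)
})

test_that("feature-table parsing rejects degenerate input", {
    expect_error(parseFeatureTable("#genome_length=10 circular=true"),
                 "no features")
    dup <- paste("a\tF\t1\t3\tPCG", "a\tF\t5\t8\tPCG", sep = "\n")
    expect_error(parseFeatureTable(dup), "duplicate")
    rev_ <- "a\tF\t9\t3\tPCG"
    expect_error(parseFeatureTable(rev_), "start > end")
})

test_that("ambiguity codes other than N are rejected at parse time", {
    expect_error(annotatedMitogenome(geneFeature("a", "PCG", "F", 1, 4),
                                     sequence = "ATRC"), "ambiguity")
    expect_silent(annotatedMitogenome(geneFeature("a", "PCG", "F", 1, 4),
                                      sequence = "ATNC"))
})

test_that("extractGeneSequence honours strand and origin wrap", {
    g <- annotatedMitogenome(geneFeature("fw", "PCG", "F", 1, 4),
                             sequence = "ATGCAAAAAA")
    expect_equal(extractGeneSequence(g, "fw"), "ATGC")
    gr <- annotatedMitogenome(geneFeature("rv", "PCG", "R", 1, 4),
                              sequence = "ATGCAAAAAA")
    expect_equal(extractGeneSequence(gr, "rv"), "GCAT")  # by hand
    # 10-bp toy genome, gene spans 9..2 through the origin: tail(2)+head(2)
    gw <- annotatedMitogenome(geneFeature("wr", "tRNA", "F", 9, 2,
                                          wraps_origin = TRUE),
                              genomeLength = 10, sequence = "ATGCAAAACG")
    expect_equal(extractGeneSequence(gw, "wr"), "CGAT")
    expect_error(extractGeneSequence(g, "nope"), "unknown gene")
})

test_that("feature-table I/O round-trips every field exactly", {
    g <- fixtureGenome()
    g2 <- parseFeatureTable(writeFeatureTable(g), label = genomeLabel(g))
    expect_identical(geneFeatures(g2), geneFeatures(g))
    expect_identical(genomeLength(g2), genomeLength(g))
    expect_identical(isCircular(g2), isCircular(g))
    for (seed in 1:3) {
        r <- randomAnnotatedGenome(seed)
        rt <- parseFeatureTable(writeFeatureTable(r))
        expect_identical(geneFeatures(rt)[, c("gene", "strand", "start",
                                              "end", "feature_class")],
                         geneFeatures(r)[, c("gene", "strand", "start",
                                             "end", "feature_class")])
    }
})

test_that("gene-order text round-trips signed names", {
    o <- geneOrder(c("cox1", "trnR-cga", "nad6"),
                   orientation = c("+", "+", "-"))
    txt <- writeGeneOrder(o)
    expect_equal(txt, "cox1 trnR-cga -nad6")
    o2 <- readGeneOrder(txt)
    expect_equal(orderGenes(o2), orderGenes(o))
    expect_equal(orderSigns(o2), orderSigns(o))
    expect_error(readGeneOrder("   "), "empty")
})

test_that("extracted lengths match the coordinate length formula; R = revcomp of F", {
    for (seed in 4:6) {
        g <- randomAnnotatedGenome(seed)
        lens <- featureLengths(g)
        for (nm in names(lens))
            expect_equal(nchar(extractGeneSequence(g, nm)),
                         unname(lens[nm]))
        ft <- geneFeatures(g)
        for (i in seq_len(nrow(ft))) {
            fSlice <- substring(genomeSequence(g), ft$start[i], ft$end[i])
            expected <- if (ft$strand[i] == "R") rcOracle(fSlice) else fSlice
            expect_equal(extractGeneSequence(g, ft$gene[i]), expected)
        }
    }
})

test_that("FASTA writer/reader round-trips a sequence", {
    f <- withr::local_tempfile(fileext = ".fa")
    seq <- randomSeq(150)
    writeFASTA(seq, f, name = "toy")
    back <- readFASTA(f)
    expect_equal(unname(back), seq)
    expect_equal(names(back), "toy")
})
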