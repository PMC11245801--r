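# shared fixtures, built in code

# independent reverse complement (kept separate from the package's helper)
rcOracle <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# a tiny sequence-bearing genome: two genes, one on each strand
toyGenome <- function() {
    seq <- paste0("ATGAAATAA",          # gA: PCG, 1..9
                  "TTTT",               # spacer
                  "GGGCCCAT",           # gB: tRNA (R), 14..21
                  "ACGTACGTA")          # tail to 30
    annotatedMitogenome(
        rbind(geneFeature("gA", "PCG", "F", 1, 9),
              geneFeature("gB", "tRNA", "R", 14, 21)),
        sequence = seq, label = "toy")
}

# random annotated genome via the generator (no overlaps, no wrap genes)
randomAnnotatedGenome <- function(seed, nGenes = 6L) {
    set.seed(seed)
    classes <- c("PCG", rep(c("tRNA", "PCG", "rRNA"),
                            length.out = nGenes - 1L))
    len <- ifelse(classes == "PCG", 3L * sample(10:40, nGenes, TRUE),
                  sample(60:90, nGenes, TRUE))
    inv <- data.frame(name = sprintf("g%02d", seq_len(nGenes)),
                      class = classes,
                      strand = sample(c("F", "R"), nGenes, TRUE),
                      length = len, stringsAsFactors = FALSE)
    plan <- sample(0:30, nGenes, TRUE)
    generateGenome(genomeSpec(inv, plan), seed = seed + 1000L)$genome
}

# minimal GenBank flat-file text
genbankRecord <- function(sequence = "ATGGCCAAATGAACGTACGT",
                          features = c(
    "     CDS             1..9",
    '                     /gene="cox1"'),
                          origin = TRUE) {
    len <- nchar(sequence)
    lines <- c(
        sprintf("LOCUS       TESTREC %19d bp    DNA     circular INV 01-JAN-2024",
                len),
        "DEFINITION  synthetic test record.",
        "FEATURES             Location/Qualifiers",
        "     source          1..20",
        '                     /organism="synthetic"',
        features)
    if (origin) {
        blocks <- substring(tolower(sequence),
                            seq(1L, len, 60L), pmin(seq(1L, len, 60L) + 59L, len))
        lines <- c(lines, "ORIGIN",
                   sprintf("%9d %s", seq(1L, len, 60L), blocks), "//")
    }
    paste(lines, collapse = "\n")
}

fixtureGenome <- function() benthodytesAnnotation()
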