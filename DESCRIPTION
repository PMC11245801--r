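Package: mitoprofile
Title: Descriptive and Comparative Analysis of Annotated Mitochondrial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for the descriptive and comparative analysis of annotated
    circular mitochondrial genomes: nucleotide composition with AT/GC skew
    statistics per gene class and codon position, codon usage and relative
    synonymous codon usage (RSCU) under the echinoderm mitochondrial genetic
    code, start/stop codon classification including incomplete stops,
    intergenic spacer and gene-overlap accounting, control-region inference
    from long unannotated gaps, and signed gene-order rearrangement
    comparison via breakpoint distances. Includes a seeded generator of
    synthetic annotated mitogenomes with known ground truth so every
    analysis stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
biocViews: Genetics, Annotation, SequenceMatching, ComparativeGenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
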