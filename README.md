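# mitoprofile

Descriptive and comparative analysis of annotated mitochondrial genomes in R.

Metazoan mitogenomes are small circular molecules carrying a near-universal
inventory of 37 genes (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus one or
more non-coding control regions. Papers describing a newly sequenced
mitogenome all report the same descriptive battery, and `mitoprofile`
implements it as tested, reusable functions for anyone characterizing such a
genome from its annotation:

- **Base composition and strand asymmetry** per gene class and codon
  position: AT%, GC%, and the skews
  `AT-skew = (A − T)/(A + T)`, `GC-skew = (G − C)/(G + C)`.
- **Codon usage** under the echinoderm/flatworm mitochondrial genetic code
  (NCBI translation table 9: AGA/AGG → Ser, ATA → Ile, AAA → Asn,
  TGA → Trp), with per-gene start/stop classification including the
  incomplete stops `T`/`TA` completed by polyadenylation, and **RSCU**
  (relative synonymous codon usage),
  `RSCU(c) = n_c · |family| / Σ_{c' ∈ family} n_{c'}`,
  with the Leu-UUR/Leu-CUN and Ser-UCN/Ser-AGN families kept separate.
- **Junction accounting**: signed intergenic gaps (negative = overlap),
  spacer/overlap totals, zero-gap gene runs, and **control-region
  inference** from long unannotated gaps, with the exact circular identity
  `Σ gene lengths + Σ spacers − Σ |overlaps| = genome length`.
- **Gene-order comparison**: cox1-anchored linearization of the signed
  circular order and pairwise breakpoint distances under the orientation
  rule `x→y ≡ (−y)→(−x)`.
- A **seeded synthetic-mitogenome generator** with full ground truth
  (layout, planted codons, composition, rearrangement events), so every
  stage is testable without downloading anything.

The package ships the published gene annotation of the deep-sea sea cucumber
*Benthodytes* sp. Gxx-2023 (GenBank OR992091; 17,386 bp) as a
coordinates-only fixture and reproduces its printed structural description
exactly.

## Worked example

```r
library(mitoprofile)

g <- benthodytesAnnotation()      # or parseFeatureTable() / parseGenBank()
g
#> AnnotatedMitogenome 'Benthodytes sp. Gxx-2023 (OR992091)'
#>   length: 17386 bp (circular, coordinates-only)
#>   features: 37 (PCG:13, tRNA:22, rRNA:2, CR:0)

s <- spacerSummary(g)
str(s[c("n_spacers", "total_spacer_bp", "n_overlaps", "total_overlap_bp")])
#> List of 4
#>  $ n_spacers       : int 22
#>  $ total_spacer_bp : int 2252
#>  $ n_overlaps      : int 3
#>  $ total_overlap_bp: int 13

inferControlRegions(g, minLen = 500)
#>   name start   end length    after   before wraps_origin
#> 1  CR1 10712 11593    882 trnE-gaa trnA-gca        FALSE
#> 2  CR2 14782 15934   1153 trnT-aca     rrnL        FALSE

circularLengthIdentity(g)$holds   # 15146 + 2253 - 13 == 17386
#> [1] TRUE

formatGeneOrder(linearizeOrder(g, includeCR = FALSE))
#> [1] "cox1 trnR-cga nad4l cox2 trnK-aag atp8 atp6 cox3 -trnS2-tca nad3 ..."
```

The 22 spacers total 2,252 bp; the three overlaps (largest 7 bp, between
atp8 and atp6) total 13 bp; the two inferred control regions are the 882-bp
gap after trnE-gaa and the 1,153-bp gap after trnT-aca; and genes on the
reverse strand (e.g. trnS2-tca, nad6) carry a `-` sign in the linearized
order.

Sequence-dependent stages run on any sequence-bearing genome — a parsed
GenBank record, a FASTA attached to a feature table, or a simulated genome:

```r
sim <- generateGenome(benthodytesGenomeSpec(), seed = 42)
compositionTable(sim$genome)      # genome / PCGs / codon positions / ...
cu  <- countCodons(sim$genome)    # codon counts, stop tally, RSCU
head(sort(rscuValues(cu), decreasing = TRUE), 3)
profileMitogenome(sim$genome)     # everything, JSON-serializable
```

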