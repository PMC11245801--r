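---
title: "Profiling annotated mitochondrial genomes: methods and conventions"
author: "mitoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling annotated mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

# Scope and data model

`mitoprofile` computes the standard descriptive battery for an annotated
circular mitochondrial genome: nucleotide composition and skew statistics,
codon usage and RSCU, start/stop codon classification, intergenic
spacer/overlap accounting, control-region inference, and signed gene-order
comparison. It deliberately does *not* annotate genes, assemble reads,
build phylogenies or run homology searches — it starts where an annotation
(GenBank record or feature table) ends.

The central object is the `AnnotatedMitogenome`: a genome length, a
circularity flag, an optional nucleotide sequence over A/C/G/T/N, and an
ordered table of features, each with a name, class (PCG, tRNA, rRNA, CR),
strand (F for the deposited strand, R for its reverse complement) and
1-based inclusive coordinates. Coordinates are 1-based inclusive
throughout, matching how mitogenome tables are printed; nothing in the
user-facing API uses half-open intervals. A genome without sequence
("coordinates-only") is first-class: every structural analysis — junctions,
spacers, control regions, gene order, the circular length identity — runs
from coordinates alone, so a printed annotation table can drive most of the
package. Ambiguity codes other than N are rejected at construction:
mitogenome assemblies are effectively unambiguous, and failing fast beats
silently skewing counts. A leading `<`/`>` on a coordinate (a partial gene
boundary) is stripped, recorded in a `partial` flag, and the printed
coordinate is used verbatim.

# Composition and skew statistics

For a sequence with base counts $n_A, n_C, n_G, n_T$:

$$\mathrm{AT\text{-}skew} = \frac{n_A - n_T}{n_A + n_T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{n_G - n_C}{n_G + n_C}.$$

Skews lie in $[-1, 1]$, are antisymmetric under reverse complement (a
property test exercises this on random sequences), and are reported as a
flagged `NA` — never 0 — when a denominator vanishes (e.g. an all-N input).
Percentages are carried at full precision internally; rounding (2 d.p. for
percentages, 5 d.p. for skews, 3 d.p. for RSCU) happens only in the JSON
report layer, where a `precision` argument controls it.

Class statistics (`classComposition`) concatenate the *coding-strand*
sequences of all class members in genome order. Two conventions deserve
emphasis because they silently change results:

- **Coding strand, not deposited strand.** For an R-strand gene the class
  concatenation uses the reverse complement of the genomic slice. Codon
  position statistics only make sense on coding strands; using F-strand
  slices is available via `codingStrand = FALSE` for sensitivity checks.
- **No overlap deduplication.** Overlapping genes contribute their shared
  bases to each gene. Class totals then equal the simple sums of the
  per-gene lengths, which is how descriptive tables are printed.

Codon-position statistics (`codonPositionComposition`) default to the
*pooled* framing: the coding sequences of all PCGs are concatenated in
genome order and the concatenation is partitioned into triplets, so every
base is included and each position holds exactly total/3 bases whenever the
pooled PCG length is divisible by 3. This is the convention under which
published position counts equal the pooled length divided by three even
though individual genes end in incomplete stop codons. The alternative
(`framing = "per-gene"`) restarts the frame at each annotated start and
uses only complete codons; on a genome with $k$ one-base incomplete stops
it drops $k$ bases. Both are exact; they answer slightly different
questions, and the pooled form is the default because it is what
descriptive tables report.

`compositionTable` assembles the standard report (genome, PCGs, positions
1–3, tRNA, rRNA, control region) plus each row's length as a percentage of
the genome. Missing classes become flagged NA rows rather than errors, so
one absent class does not take down the report.

# Codon usage, start/stop classification and RSCU

The genetic code defaults to NCBI translation table 9 (echinoderm/flatworm
mitochondrial: AGA/AGG → Ser, ATA → Ile, AAA → Asn, TGA → Trp), obtained
from Biostrings, giving 62 sense codons and two stops (TAA, TAG).
Synonymous families follow codon-usage plotting convention: Leu is split
into Leu-UUR (TTA/TTG) and Leu-CUN, Ser into Ser-UCN and Ser-AGN (four
codons each under table 9); `merged = TRUE` collapses the pairs for
sensitivity analyses, since published RSCU values do not always say which
convention the authors' tool used.

Start codons are reported verbatim (first triplet — mitochondrial PCGs use
ATG but also ATT and others; nothing is re-called). Stops are classified
as: the final complete triplet when it is TAA/TAG and the gene length is a
multiple of 3; otherwise a non-empty 1- or 2-base remainder is an
incomplete stop `T`/`TA` (completed to TAA by polyadenylation); a gene
ending in a non-stop complete triplet is flagged anomalous rather than
rejected, since annotation errors should surface, not crash.

Codon counting pools all PCGs. Stop triplets and incomplete tails are kept
in a separate stop tally and excluded from amino-acid counts and RSCU.
$\mathrm{RSCU}(c) = n_c \cdot |F_c| \,/\, \sum_{c' \in F_c} n_{c'}$; family
sums equal family sizes whenever the family was observed (asserted on every
construction via the class validity method), and unobserved families give
flagged NA rather than 0. Amino-acid percentages use the total of counted
(non-stop) codons as denominator; published percentages sometimes imply
slightly different denominators (with or without stops or start codons),
so the counts are the primary output and the percentage is explicitly
convention-dependent.

# Junction accounting and control-region inference

Junctions are computed between consecutive non-CR genes sorted by start:
$\mathrm{gap} = \mathrm{start}_{\mathrm{down}} - \mathrm{end}_{\mathrm{up}} - 1$,
so positive gaps are spacers, negative gaps overlaps, and the gap is
attributed to the junction *before* the downstream gene (the column
convention of printed tables). On circular genomes the wrap junction (last
gene back to the first through the origin) is computed and flagged. Three
deliberate choices:

- **The wrap junction is excluded from spacer totals by default**
  (`includeWrap = FALSE`): printed spacer accountings enumerate the gap
  column of the annotation table, which starts at the second gene, and
  demonstrably omit the wrap gap. The flag restores it; the circular
  length identity always includes it.
- **Opposite-strand overlaps count as overlaps** — an overlap is a property
  of coordinates, not strands.
- **Nested genes are rejected** with the offending pair named. Junction
  chains are ill-defined under nesting, and no real mitogenome annotation
  of this shape nests genes; silently merging would corrupt totals.
  Likewise, junction analysis requires that no gene spans the origin —
  deposited annotations are rotated so none does.

Ties for largest spacer/overlap break to the first occurrence in genome
order, making reports deterministic. Zero-gap runs are maximal sets of ≥2
consecutive genes joined by exactly-zero gaps; the count of genes
participating in such runs is the figure descriptive papers quote as genes
"without gaps". The exact circular identity
$\sum \mathrm{lengths} + \sum \mathrm{spacers} - \sum |\mathrm{overlaps}|
= L$ is exposed by `circularLengthIdentity()` and asserted in the tests.

Control regions are the long non-coding stretches of the molecule; since
annotations frequently do not list them, `inferControlRegions()` promotes
every junction gap ≥ `minLen` (default 500 bp — well above tRNA-sized gaps,
well below real control regions, and large enough that typical spacers
never reach it) to a CR interval with explicit coordinates.
`addInferredControlRegions()` appends them as CR features so CR composition
and CR-aware gene orders work on plain annotations.

# Gene-order comparison

Orders are compared as signed sequences. `linearizeOrder()` rotates the
circular order so an anchor gene (cox1, the conventional starting point — the most
conserved PCG) comes first with + orientation, flipping the entire order
(reverse + sign inversion, the circular mirror) when the anchor lies on the
reverse strand. Control regions enter as pseudo-genes by default
(`includeCR = TRUE`), since multi-CR genomes are a reportable feature of
the order; both that and tRNA exclusion (tRNAs are the most mobile
elements) are caller-controlled by subsetting or flags.

`compareOrders()` restricts both orders to their shared gene set (private
genes are reported, never silently dropped), forms oriented adjacency sets
under the rule $x \to y \equiv (-y) \to (-x)$, and counts breakpoints as
adjacencies of one order absent from the other; because both restrictions
have equal length the count is symmetric, zero exactly for identical signed
sequences. The package reports breakpoint distances and flags only
*candidate* event types (a moved same-sign gene suggests transposition, a
sign change inversion); full event-history inference (TDRL, DCJ sorting) is
out of scope because descriptive comparisons do not perform it. A single
excise-and-reinsert transposition changes at most three adjacencies, so the
distance after $k$ planted transpositions is bounded by $3k$; the property
tests assert this bound, symmetry, and zero-iff-identical. No reference
("ground pattern") gene order is hard-coded; comparisons run against
whatever orders the user supplies.

# The synthetic-genome generator

`genomeSpec()`/`generateGenome()` emulate exactly the statistical structure
the analyses measure: a gene inventory laid around a circle by a signed
junction plan (so spacer/overlap layouts, zero-gap runs and long CR gaps
are planted with known ground truth); intergenic, tRNA and rRNA sequence
drawn i.i.d. from target base frequencies; PCGs drawn codon-by-codon —
never base-by-base — so within-family codon proportions are directly
controllable and internal stops cannot arise; planted start codons; stops
realized as TAA/TAG when the gene length is divisible by 3 and as
incomplete `T`/`TA` otherwise (so incomplete stops are planted by choosing
lengths ≡ 1 or 2 mod 3, exactly how they arise in real annotations).
Reverse-strand genes are written as reverse complements on the deposited
strand. When no codon weights are given they default to the product of the
target base frequencies over the codon's bases, so coding regions also
approximate the requested composition. Gaps of ≥ 500 bp can be given a
distinct, typically AT-richer, control-region composition.

Where genes overlap, the downstream gene's bases win at assembly, and the
ground-truth start/stop codons are then *re-read from the assembled
sequence*, so the returned ground truth is always consistent with the
emitted genome (an upstream stop inside an overlap may be overwritten —
as in real overlapping gene pairs, which share sequence).

Everything is seed-parameterized; identical spec + seed gives byte-identical
output, and rearrangement simulation (`permuteOrder`) emits a replayable
event log.

`benthodytesGenomeSpec()` mirrors the shipped annotation of the
*Benthodytes* sp. Gxx-2023 mitogenome — its 37-gene inventory, every gap
and overlap including the two long CR gaps, its start codons, and base
frequencies matching that genome's printed composition (A 31.35%, C
18.70%, G 13.44%, T 36.51%; AT-richer CR frequencies) — so simulated
genomes share its full structural layout with a synthetic sequence.

What the generator does **not** emulate: positional autocorrelation
(real sequence is not i.i.d.), amino-acid composition of real proteins,
tRNA/rRNA secondary structure, strand-specific mutational gradients along
the molecule, and repeat structure inside control regions. Passing tests
on generator output therefore validate the *bookkeeping and statistics* of
the analyses — exact recovery of planted structure, correct estimators of
planted composition — not biological realism of the sequence itself, and
sequence-specific published values (skews of a particular deposited
record, its codon counts) can only be checked against the record itself.

# Numerical and degenerate-input choices

- Empty sequences, empty feature tables, duplicate gene names, unknown
  genes, absent classes, and anchor genes missing from an order are
  errors with actionable messages; flags (`partial`, `anomalous`,
  flagged-NA skews/RSCU) are reserved for data oddities worth reporting
  but not fatal.
- `profileMitogenome()` converts block-level errors into flags so one
  failing stage (e.g. composition on a coordinates-only genome) never
  hides the others, and its JSON serialization is deterministic: fixed
  block order, no timestamps.
- All randomness flows through explicit seeds.

# Problem sizes in the test suite

The suite exercises: the shipped 37-gene annotation (structural numbers
asserted exactly); simulated genomes of 17,386 bp mirroring it
(compositional tolerances: AT% within 2 points at that scale); i.i.d.
sequences of 10,000 nt for composition recovery (skews within 0.03); a
9,000-nt CDS for the RSCU concentration law (tolerance 0.2); 1,000 random
sequences for skew antisymmetry; and randomized 37-gene orders with 1–6
planted events for breakpoint properties. These sizes make the full suite
run in well under a minute while keeping the statistical assertions
comfortably inside their sampling error.

# Known limitations

- GenBank parsing targets single-record flat files with simple
  (`complement`, two-segment `join`) locations — enough for deposited
  mitogenomes, not a general GenBank parser.
- The feature-table dialect cannot express origin-wrapping genes (the
  object model can; rotate the annotation instead).
- Junction analysis requires non-nested, non-origin-spanning genes.
- Event classification beyond breakpoint distance is heuristic by design.
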