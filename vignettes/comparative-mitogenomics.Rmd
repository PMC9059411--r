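---
title: "Comparative mitogenomics with mitocomp: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitocomp` compares panels of circular, annotated fungal mitochondrial
genomes: composition and strand skews, region budgets and their
contribution to genome-size differences, codon usage under the mold
mitochondrial genetic code, K2P and NG86 evolutionary rates, repeat
content, group-I intron position-class homology, circular gene-order
rearrangement, and a distance-based supermatrix phylogeny. This
vignette explains the models behind each stage, the parameters that
matter, and the design decisions taken where the methods literature
leaves choices open.

## The data model

A `MitoGenome` is a circular (or linear) uppercase DNA string plus an
ordered list of typed, stranded features. Coordinates are 1-based
inclusive, the GenBank convention, everywhere. A feature's exons are
stored in ascending genome order; transcription order is derived from
the strand, so a minus-strand two-exon gene reads its highest-
coordinate exon first, reverse-complemented. On circular genomes an
exon may span the origin, encoded as `start > end`; the GenBank writer
re-splits such exons into a `join(x..L,1..y)` and the reader merges
them back, so round-trips are exact.

Ambiguity codes other than `N` are rejected at parse time: the
deposits this package targets are unambiguous, and a hard error beats
a silently skewed statistic. `N` participates in no statistic — it is
excluded from composition denominators, codon counts (tallied as
skipped), and distance columns.

Translation uses NCBI table 4 (TGA = tryptophan; TAA/TAG the only
stops) by default, overridable per call — the distinguishing case is
TGA/TGG, a *synonymous* difference under table 4 and a stop/Trp
non-comparison under the standard code.

## Region budgets and contribution rates

Every genomic position is assigned to exactly one category under the
precedence rule

> protein-coding exon > intron > rRNA > tRNA > rnpB > intergenic,

with overlapping positions counted once in the higher-precedence
category. Annotation deposits do not state how overlaps should be
budgeted, so some rule must be declared for percentages to be
well-defined; this one keeps coding sequence primary and makes totals
tile the genome exactly, which in turn makes the contribution rate of
a category to a size difference,

\[(\Delta\,\mathrm{region\ bp})/(\Delta\,\mathrm{genome\ bp}) \times 100\%,\]

sum to exactly 100 over categories for every genome pair — an
algebraic identity the tests assert. Categories can shrink while the
genome grows, so individual rates may be negative.

## Alignment

Pairwise global alignment uses affine gap costs where a gap of length
$L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$ (defaults: nucleotide
match +1 / mismatch −1 / open −4 / extend −1; protein BLOSUM62 with
open −10 / extend −1). The DP engine is `Biostrings::pairwiseAlignment`;
scores are recomputed locally from the returned rows under the stated
convention, and the suite checks optimality against an independent
three-matrix DP oracle on exhaustive short random pairs. Codon-aware
alignment aligns the table-4 translations and back-projects protein
gaps as whole-codon gaps, so alignment columns group into codons; a
terminal stop codon is dropped before alignment.

Multiple alignment is deliberately avoided. The consumers that matter
— intron-site projection and the supermatrix — use pairwise alignment
to a designated reference, with rows merged on reference coordinates
(insertions relative to the reference are dropped). That is a
reference-anchored pseudo-MSA: adequate for distance-based trees and
site projection on conserved core genes, and a documented divergence
from progressive aligners like MAFFT, whose columns it will not
reproduce.

## Evolutionary rates

**K2P.** Over gap- and N-free columns with transition proportion $P$
and transversion proportion $Q$, Kimura's closed form
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. Columns are removed
pairwise (complete deletion within each pair). A non-positive log
argument flags the pair saturated; saturated pairs are excluded from
panel means and reported. The implementation is cross-checked against
`ape::dist.dna(model = "K80")` in the tests.

**NG86 Ka/Ks.** Classic Nei–Gojobori counting: each codon position
contributes its fraction of synonymous one-step changes to the
synonymous site count, with mutations to stop codons excluded from the
per-position denominator (so synonymous + nonsynonymous sites = 3 per
codon, a conservation law the tests assert). Differences between a
codon pair are averaged over all minimal mutational pathways,
excluding pathways through stops; in the rare case that every path
crosses a stop, all paths are used rather than dropping the codon
silently. $p_S$ and $p_N$ receive the Jukes–Cantor correction
$K = -\tfrac34\ln(1-\tfrac43 p)$, with $p \ge \tfrac34$ flagged
saturated. Ka/Ks is null (not 0, not $\infty$) when Ks = 0, and nulls
are excluded from means. NG86 ignores transition/transversion bias by
construction, so under a transition-biased neutral process it reports
Ka/Ks below 1 (≈0.78 at $\kappa=4$ in the suite's simulation); that is
a property of the estimator, not a bug, and matches its behavior in
DnaSP-style analyses.

Panel summaries average all unordered genome pairs carrying the gene —
the one-number-per-gene view used to rank core genes by divergence and
selection.

## Repeats

Interspersed repeats come from an exact k-mer (default k = 11)
self-comparison on both strands, with seeds grouped by diagonal and
extended by ungapped X-drop extension; hits shorter than `min_len`
(default 40 bp) or below `min_identity` (default 70%) are discarded,
and the trivial self-diagonal and duplicate/contained hits are
removed. Circularity is honored by scanning the sequence with its
first 2 kb appended and folding hits modulo the genome length. The
defaults approximate a stringent BLASTn self-search regime at the
30–70 kb scale of these genomes; e-values themselves are deliberately
not reproduced — the validated surface is planted-repeat recovery
(100% of exact duplications ≥ 40 bp; ~0 false positives in random
10-kb sequence), and reported identities are re-derived from the
spans, so every reported pair is independently checkable.

Tandem arrays are found per candidate period $p$ (1–200) by comparing
the sequence with itself shifted by $p$: maximal agreement runs
(merged across single mismatches while identity stays ≥ 90%) of total
length ≥ 11 bp and ≥ 2 copies. Units are canonicalized to their
lexicographically smallest rotation, and arrays explained by a smaller
period are suppressed. Repeat coverage is always a union of positions,
never a sum, so overlapping repeats are not double-counted.

## Intron position classes

An intron's identity across species is its insertion site on a shared
coordinate system: the spliced CDS of a reference gene. For each
genome, intron offsets (cumulative spliced exon lengths at each
junction, in transcription order) are projected through the
codon-aware alignment onto the reference, and the class is named
`P<reference offset>`. Offsets are *ungapped reference* nucleotide
positions, and the merge tolerance defaults to 0 nt (exact aligned
position), configurable to ±3 for noisy annotations — class names are
exact positions, so exactness is the default. Projections that land in
a reference gap are flagged unmappable and reported, never silently
dropped; assignment is reference-anchored and therefore independent of
the order genomes are processed in.

A class present in strictly more than one fifth of the compared
species is labeled *common*, otherwise *rare* (with $n = 17$, presence
in 4 species is common, 3 is rare).

Validated recovery: with divergence up to 0.2 substitutions/site and
2% codon indels, ≥ 95% of planted insertion sites recover their exact
planted reference offset (the acceptance script measures ~99% over 50
seeded panels). The reference CDS is user-supplied; any intronless (or
spliced) homolog works, and the choice anchors only the naming, not
the grouping.

## Gene order

The circular order of the 15 core genes plus the two rRNAs is read off
by start coordinate. Two rearrangement statistics are computed over
the shared gene set of a pair: **adjacency breakpoints** — unordered
neighbor pairs on the circle present in one order but not the other —
and **positional changes** — genes whose left/right neighbor pair
differs. Adjacency is strand-insensitive by default (deposit strand
conventions vary; a signed mode is a flag away), and
identical-arrangement grouping treats rotations and, by default,
reflections as equal, because a circular molecule has no canonical
origin or reading direction. "Positional change" has no standard
definition in the comparative literature; the neighbor-pair
operationalization is declared here and checked against brute-force
adjacency enumeration on all permutations of up to 6 genes.

## Supermatrix and tree

Per-gene reference-anchored alignments are concatenated with
gap-filling for missing taxon×gene blocks and an exact partition
table; exports are relaxed PHYLIP, FASTA and a RAxML-style partition
file, so model-based inference can be run elsewhere on the same
matrix. The in-package tree is neighbor joining on the pairwise K2P
matrix (pairwise-complete columns): deterministic lowest-index
tie-breaks, negative branch lengths clamped to zero and counted in the
`clamped` attribute. On additive matrices NJ is exact — topology and
branch lengths — which the suite verifies on 100 random 5–8 taxon
trees; it is a desk-scale, deterministic stand-in, not a substitute
for Bayesian or ML inference with support values.

## The synthetic generator

`build_panel()` emulates the statistical structure the analyses
assume: a circular ancestor (~23–30 kb by default, GC 35%) carrying
the 15 core PCGs with realistic lengths (e.g. *cox1* 1593 nt, *nad5*
1980 nt, *atp9* 225 nt), two rRNAs, rnpB and 22 tRNAs in a random
order with ~20% minus-strand genes and negative-binomial intergenic
spacers sized to the target length. Each panel genome sits at
`divergence/2` from the ancestor under a K2P process with
transition/transversion rate ratio `kappa` (default 2), so every
genome pair is separated by `divergence` substitutions/site in
expectation. CDS bodies mutate codon-wise with stop-creating draws
resampled (start and terminal stop codons held fixed), keeping Ka/Ks
analyses interpretable; non-coding sequence mutates unconstrained.
Codon indels, intron insertions at planned spliced offsets (annotated
as multi-exon features, with indel-shifted realized offsets recorded),
repeat plants and gene relocations are all applied through a layout
representation, so the emitted sequence, feature coordinates and truth
record cannot drift apart. Every realization is reproducible from the
seed, down to byte-identical files on disk.

What the generator does *not* emulate: realistic intron sequence
models (homing-endonuclease ORFs), recombination, tRNA structure,
compositional heterogeneity along the genome, or annotation error.
Passing the recovery suite therefore demonstrates correctness of the
measurement machinery under the stated generative model, not
robustness to mis-annotated real deposits — for real data the
pipeline trusts the deposited annotation as-is.

## Numerical and degenerate-input choices

* Skews with a zero denominator report 0 with a definedness flag
  rather than NaN.
* Stop codons are counted in the start/stop table and excluded from
  the 64-codon frequency normalization; codons containing N are
  skipped and tallied.
* Saturated distances report `Inf` plus a flag and are excluded from
  means; Ka/Ks with Ks = 0 is `NA`.
* Alignment traceback ties are resolved deterministically; NJ Q-matrix
  ties take the lowest index pair. Identical inputs give byte-identical
  outputs throughout the pipeline (asserted in the tests).
* Equal-length genomes have no defined contribution rates (error), a
  single genome degrades pairwise stages to explicit
  "insufficient genomes" notes, and an unknown pipeline stage lists
  the valid ones.

## Problem sizes used in validation

The suite and the acceptance script run entirely on generated data:
10-kb sequences for distance-estimator calibration (bias < 5% at
d ∈ {0.01, 0.05, 0.2}), 23.5-kb genomes in 2–5 genome panels for
end-to-end stages, 50 seeded panels for intron-site recovery, 25
planted-repeat fixtures plus 20 negative controls, 100 random additive
matrices for NJ, and all 720 permutations of a 6-gene circle for the
breakpoint oracle. These sizes give tight Monte-Carlo error on every
asserted quantity while keeping a full validation run in the order of
a minute.

## Known limitations

* The GenBank parser covers the organellar-deposit subset of the
  format (LOCUS topology, join/complement locations, gene/product
  qualifiers); exotic location operators are rejected with an error
  naming the feature.
* Reference-anchored pseudo-MSAs drop insertions relative to the
  reference; column sets are not those of a progressive MSA.
* The repeat finder's ungapped extension slightly over- or under-runs
  repeat boundaries compared to a gapped local aligner; identities are
  exact for the reported spans.
* NJ provides no support values; export the supermatrix for MrBayes /
  RAxML when supports are needed.
* Intron group typing (I vs II) is read from annotation when present,
  never inferred from sequence.
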