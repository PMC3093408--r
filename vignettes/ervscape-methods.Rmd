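---
title: "Methods: models, parameters and design choices in ervscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ervscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscape)
```

This vignette is the package's own account of its science: the models
behind each analysis, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The input: proviral chains

Genome screening software reports candidate endogenous retroviruses as
*chains* — ordered retroviral motif hits (LTR–gag–pro–pol–env–LTR) with
a detection score, a genus call, reconstructed "putein" protein
sequences per gene, LTR sub-features and a primer-binding-site (PBS)
label.  The screening step itself is out of scope here; the package
consumes a documented TSV dialect (`read_chain_table()`) that carries
one chain per row with its sub-features as typed columns.  Because no
public on-disk format exists for this kind of output, the dialect is
defined by this package and should be treated as such.

Internally every coordinate is 0-based half-open.  GFF3 and AGP
(1-based closed) and RepeatMasker `.out` are converted exactly once on
read and restored on write; strandless gene features are rejected rather
than defaulted, because the neighborhood analysis is meaningless without
orientation.

## Filtering and the one-chain-per-locus cascade

Two filters act on chains directly:

* **Score** (`filter_by_score`, default threshold 300, strict `>`).
  Detection scores above 300 separate real chains from chance motif
  arrangements with a comfortable margin; the comparison is strict, so a
  chain scoring exactly 300 is removed.
* **Locus deduplication** (`dedup_loci`).  The notion of "locus" is not
  formally defined by chain detectors; here it is the transitive closure
  of ≥ 1 bp span overlap on one chromosome — the simplest reading under
  which "lower scoring elements in the same locus" is well defined.
  Within a locus the survivor is chosen by (1) the greatest number of
  *distinct* putein genes, then (2) the greatest total number of
  annotated puteins, then (3) the highest score.  Residual ties (possible
  in synthetic data) fall deterministically to the smallest start
  coordinate, then smallest id.

Sequence QC flags rather than deletes: puteins with **five or more**
undetermined (`X`) residues fail (`qc_puteins`), and LTRs with **15 or
more** ambiguous (non-ACGT) nucleotides fail (`qc_ltrs`).  The 15-nt LTR
rule is an interpretation — the criterion is stated in the literature
without a definition (minimum length? ambiguity cap? indel run?) — so it
is implemented as an ambiguity cap with a configurable threshold and
flagged as such.  Chains whose LTR pair fails QC are carried through
dating as `undatable`, never silently dropped.

## LTR-divergence dating

At integration the two LTRs of a provirus are identical copies; after
fixation each accumulates neutral substitutions independently.  The
package dates integrations with a deliberately *uncorrected* linear
clock:

* divergence *d* = gap- and ambiguity-excluded p-distance between the
  aligned 5' and 3' LTRs (`ltr_divergence`);
* age *t* = *d* / (2 *r*), with *r* = 0.002 substitutions/site/Myr per
  lineage (`dating_config`), the factor 2 reflecting the two
  independently diverging lineages (explicit and configurable as
  `lineages`);
* classes: young *d* < 0.05, middle 0.05 ≤ *d* ≤ 0.10 (both bounds
  inclusive), old *d* > 0.10.

No Jukes–Cantor or Kimura nucleotide correction is applied: the clock's
published anchor arithmetic (5% → 12.5 Mya, 10% → 25 Mya at 0.2%/Myr)
is linear in the raw p-distance, and reproducing those anchors exactly
takes precedence over multiple-hit correction at these shallow
divergences.  Consequently ages beyond ~50 Myr are increasingly
underestimates on real data.  A second, smaller high-divergence effect
comes from the aligner itself: near 40% divergence the affine
Needleman–Wunsch occasionally scores a gapped alignment above the
true (gap-free) one, hiding mismatches inside gap columns and biasing
the gap-excluded p-distance down by about 1% relative — well inside
the per-pair binomial sampling error for a 400-nt LTR, but visible in
large replicate means.

Alignment (`align_ltrs`) is Needleman–Wunsch global with affine gaps
(match +2, mismatch −1, gap open −5, gap extend −1), computed by
`Biostrings::pairwiseAlignment`; the score is verified in the test suite
against an exhaustive three-state dynamic program.  Tie-breaking between
equal-scoring alignments follows the library's deterministic choice;
this can only matter for the divergence of pathological exact-tie
alignments.

## The gene neighborhood

**Composite models.**  Per gene, the longest transcript is selected and
any alternative transcript that overlaps the growing model and extends
it is annexed, iteratively (`build_composite_models`).  The result is
the union interval of the overlap-connected component containing the
longest transcript; a non-overlapping alternative transcript is *not*
annexed.  Genes with transcripts on both strands split into two models
with a warning.

**Profile.**  `neighborhood_profile()` counts *nucleotides of composite
models*, not gene tallies, at each signed offset in a ±100 kb window
around every ERV (the published y-axis is ambiguous between the two
readings; the nucleotide reading matches the statistic's description of
"total number of nucleotides").  Offsets are measured from the ERV's
edges in the ERV's own frame: +1 is the first basepair downstream of
the 3' LTR, −1 the first upstream of the 5' LTR, and every model
basepair overlapping the ERV is pooled at offset 0.  Two consequences
are worth stating plainly:

* position 0 aggregates entire overlaps, so its count may exceed the
  number of gene models — every other position is bounded by it;
* because the frame is the ERV's, flipping the strand of every feature
  *mirrors* the window: the arrays reverse around offset 0, and flipping
  only ERV strands swaps sense and antisense *and* reverses.  Both
  properties are enforced in tests against a per-basepair oracle.

A position covered by two gene models counts twice — the curves are
sums over (ERV, model) pairs.

**Over/under statistic.**  `over_under()` counts window positions where
the antisense curve exceeds the sense curve and vice versa and computes
a 1-df goodness-of-fit χ² on (over, under) against 50:50, excluding
equal positions.  This reproduces the published construction, but it is
*descriptive*, not inferential: adjacent positions are strongly
autocorrelated (the sign changes only at model edges), so under a true
null its variance is inflated by the typical run length and the test
rejects almost surely.  That is consistent with the enormous χ² values
such analyses print, and it is why the package also provides
`over_under_by_erv()`: for each ERV, total sense vs antisense coverage
in its window decides "over" or "under", and the χ² is computed across
ERVs — near-independent sampling units.  All calibration claims
(type-I error ≈ 5%, high power against a planted 80% antisense bias)
are made, and tested, for the ERV-unit statistic only.  The choice of
unit is a constructor argument of the analysis, not a hidden switch.

**Proximal genes.**  `proximal_genes()` reports models containing an
ERV and ERVs within 5 kb (inclusive, edge-to-edge) of a model's 5' or
3' end, with relative orientation — the "promoter-region integration"
table.

## Chromosomal landscape

`genome_fraction()` is total deduplicated chain length over genome
length as a percent (3.7 Mbp in 2.5 Gbp → 0.148%, i.e. 0.15% at two
decimals).  `bin_density()` uses half-open 1-Mb bins and assigns a
feature to the bin containing its start — ERVs are three orders of
magnitude shorter than a bin, so splitting is not worth the complexity.
`telomere_distances()` reports the minimum feature distance to each
chromosome end (0 = telomeric integration).  `region_breakdown()`
labels each ERV basepair exactly once with precedence CDS > UTR >
intron > intergenic; the precedence is a determinism choice, not a
published rule.  `correlate_counts()` is ordinary least squares with
caller-named outlier exclusion — mirroring the judgment call of
excluding the largest chromosomes rather than automating outlier
detection.

## Assembly gaps

A gap can hide an unassembled provirus.  `classify_gaps()` marks a gap
as a possible ERV-containing gap iff its AGP type is neither `clone`
nor `contig` (those gaps have assembly-logistic causes), it is not
confidently sized below 1 kb, and no SINE/LINE/simple-repeat fragment
lies within the flank window (default 50 bp) of either edge.  Two
interpretations are built in deliberately:

* AGP v2.0 unsized (`U`) gaps have placeholder lengths, so they are
  never excluded on size — "confidently sized too small" cannot apply;
* LTR-class repeats at a flank do *not* disqualify a gap: a truncated
  provirus is exactly what the analysis is looking for.

The flank distance is not specified anywhere in the source material; 50
bp ("clearly flanked") is the package's operationalization and is
configurable.  Tightening either threshold provably never increases the
candidate count, and the classifier recovers planted candidacy exactly
on synthetic assemblies.

## Pol-putein phylogenetics

Distances use per-pair gap exclusion ("pairwise deletion") and the
Kimura amino-acid correction *d* = −ln(1 − p − 0.2p²), which saturates
at p ≈ 0.854; saturated pairs are `NA` and `nj_tree()` refuses matrices
containing them rather than guessing.  Neighbor joining is implemented
from the Saitou–Nei/Studier–Keppler recurrences with two deterministic
policies: Q-matrix ties break to the lowest row-major index pair, and a
negative branch length is clamped to zero with the deficit moved to the
sister branch (preserving the joined pair's path length).  `ape`
provides the tree container and Newick I/O and serves as an independent
cross-check in the tests, never as the implementation.
`bootstrap_support()` resamples alignment columns with replacement and
reports, per internal edge, the fraction of replicate trees containing
the same bipartition; a fixed seed makes supports bit-reproducible.
Multiple alignment is an *input* throughout — reimplementing an MSA
engine is out of proportion to what the analysis adds — and the
identity matrices (`identity_matrix`) compute global identities on the
provided alignment, so they will differ from identities quoted from
local alignment methods.

`dot_matrix()` is the classical windowed self/cross comparison (cell
(i, j) true when the two windows agree at ≥ `min_identity`), used to
screen candidate proviruses for segmental duplication and
recombination; plotting is `image()`-based.

## The synthetic-data generator

`simulate_genome()` emulates the annotation *structure* the analyses
assume, not sequence realism: ERVs are placed without overlap on a small
multi-chromosome genome; each carries a random ancestral LTR mutated
into a 5'/3' pair; puteins are random amino-acid strings with a
configured rate of heavily degraded (≥ 5 X) sequences; genes are placed
around randomly chosen ERVs with a configurable antisense bias and
overlapping alternative transcripts; repeats are interspersed (kept away
from gap flanks so planted gap truth stays exact); and an AGP tiling
carries gaps of mixed types, sizes, sizedness and planted flanking
repeats.  Every planted value — true age and divergence per ERV, gene
orientation relative to its ERV, gap candidacy — is recorded in a
ground-truth sidecar, and a fixed seed makes all outputs byte-identical.

The LTR mutation model deserves one paragraph.  The number of differing
sites between the pair is drawn as Binomial(L, 2·rate·age) and each
differing site is substituted in one randomly chosen lineage — i.e.
substitutions only, no indels, no homoplasy, no back-mutation.  Realized
divergence is therefore exactly unbiased for 2·rate·age, matching the
linear clock used for dating; a naive per-lineage-per-site scheme would
introduce homoplasy whose downward bias (expected p-distance
2q − (4/3)q² rather than 2q) is visible at old ages and would make
"recover the planted age" an incoherent target.  The flip side is that
the generator cannot exercise multiple-hit saturation — a real
limitation of old-element dating that passing tests say nothing about.

Other things the generator does not emulate, hence things the test
suite cannot certify on real data: solo LTRs, nested or truncated
elements, GC/CpG rate heterogeneity, realistic gene density or exon
structure (region-breakdown inputs are synthesized separately in tests),
and phylogenetically structured ERV families (puteins are star-random;
an additive-matrix construction covers tree inference instead).

Default study conditions (chosen once as a realistic desk-scale
miniature and not revisited): 4 chromosomes × 3 Mbp, 40 ERVs of 5–10 kb
with 400-bp LTRs, ages drawn from {0, 2, 12, 25, 100} Mya at rate
0.002/site/Myr, 60 genes of 2–30 kb with 1–3 transcripts within
±100 kb of their ERV, antisense bias 0.5 (the unbiased null), 20 gaps
of 0.2–5 kb (60% fragment / 20% clone / 20% contig, 10% unsized, 30%
with a planted flanking repeat), and 30 background repeats per Mbp.

## Validation problem sizes and numerical choices

The acceptance-grade checks run at: 200 replicates × 5 age strata of
400-nt LTR pairs (mean recovered age within 3× the per-pair binomial
standard error per stratum); 1000 random locus clusters against a
brute-force cascade oracle; a 10-ERV/20-model fixture against a
per-basepair profile oracle plus 50 random fixtures for
conservation/symmetry; 200 simulations per condition for over/under
calibration — 150 ERVs and 150 genes per simulation with ERV windows
*isolated by construction* (inter-ERV spacing exceeds the analysis
window plus the maximal gene extent), since overlapping windows let
neighbors' randomly-oriented genes dilute the planted bias and the
experiment would no longer measure the planted parameter; 50
random additive 5-taxon matrices against exhaustive least-squares
topology search (15 topologies, ordinary LS on the path design matrix)
plus exact recovery at 4 and 6 taxa; and 100 simulated assemblies for
the gap classifier.  Least-squares agreement is asserted on *additive*
matrices only: for arbitrary dissimilarities NJ does not minimize
squared error, so "agreement with exhaustive search" is only a
well-posed oracle where a generating tree exists.

Remaining numerical conventions: χ² statistics use the closed-form 1-df
goodness-of-fit expression (`pchisq` for p-values); divergence of an
alignment with zero comparable columns is `NA` (undatable), as is a
saturated Kimura distance; `bin_density` bins are half-open so no
feature is counted twice; and all set operations on intervals go
through `IRanges` after the single coordinate-convention shift.
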