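# ervscape

Genome-landscape analysis of endogenous retroviruses (ERVs) in R.

Endogenous retroviruses are remnants of germ-line retroviral infections,
inherited vertically and detectable in genome assemblies as "proviral
chains": ordered runs of retroviral motifs (LTR–gag–pro–pol–env–LTR).
Screening software emits thousands of candidate chains per genome;
turning that raw output into biology requires a chain of downstream
analyses, and that chain is what this package implements:

* **Filtering** — keep chains with detection score > 300, collapse
  overlapping chains to one per locus by a three-stage cascade (most
  distinct putein genes, most total puteins, highest score), and
  quality-control reconstructed proteins ("puteins": ≥ 5 undetermined
  residues fail) and LTRs (≥ 15 ambiguous nucleotides fail).
* **LTR-divergence dating** — the two LTRs of a provirus are identical
  at integration and drift apart afterwards. With gap-excluded
  p-distance *d* and a neutral rate *r* = 0.2%/site/Myr per lineage,
  the integration age is *t = d / 2r*, so 5% divergence ≈ 12.5 Mya and
  10% ≈ 25 Mya; ages classify integrations as young (*d* < 5%), middle
  (5–10%) or old (> 10%).
* **Gene-neighborhood profiling** — per-gene composite
  ("pseudo-transcript") models are built from the longest transcript
  plus overlapping alternatives; their nucleotide coverage is histogrammed
  over a ±100 kb window around each ERV in the ERV's own reading frame,
  split into sense and antisense, with over/under χ² statistics for
  orientation bias and age-stratified variants.
* **Chromosomal landscape** — genome fraction, 1-Mb bin densities,
  telomere distances, exonic/UTR/intronic/intergenic breakdown, and OLS
  correlation of per-chromosome counts with covariates.
* **Assembly gaps** — AGP gaps classified as possible ERV-containing
  when they are not clone/contig gaps, not confidently sized < 1 kb,
  and not flanked by a non-ERV repeat (SINE/LINE/simple repeat).
* **Pol phylogenetics** — nt/aa identity matrices, Kimura-corrected
  protein distances *d* = −ln(1 − p − 0.2p²), hand-rolled Saitou–Nei
  neighbor joining with bootstrap supports, and dot-matrix screening.
* **Synthetic data** — `simulate_genome()` produces every input the
  pipeline consumes (chain table, LTR FASTA, GFF3 genes, repeat BED,
  AGP) with ground-truth sidecars, so each analysis can be validated
  against planted truth.

All coordinates inside the package are 0-based half-open; GFF3, AGP and
RepeatMasker input is converted once at the I/O boundary.

## Worked example

```r
library(ervscape)

sim <- simulate_genome(sim_config(seed = 42))
sim
#> sim_genome: 4 chromosome(s), 40 ERV(s), 60 gene(s), 20 gap(s)

# filter + dedup, then date every chain from its LTR pair
chains <- dedup_loci(filter_by_score(sim$chains))
dated  <- date_ltr_pairs(chains, sim$ltr_seqs)
head(dated[, c("chain_id", "divergence", "age_mya", "age_class")], 3)
#>   chain_id divergence age_mya age_class
#> 1        1  0.0400000   10.00     young
#> 2        2  0.4160401  104.01       old
#> 3        3  0.0000000    0.00     young

# sense/antisense gene neighborhood within +/-100 kb
models <- build_composite_models(sim$transcripts)
prof <- neighborhood_profile(chains, models)
over_under(prof)
#> over/under (unit = position): over = 104819, under = 51141, equal = 44041
#>   chi-square(1) = 18474.79, p = 0
over_under_by_erv(chains, models)     # calibrated, ERV as sampling unit
#> over/under (unit = erv): over = 19, under = 13, equal = 8
#>   chi-square(1) = 1.125, p = 0.2888444

genome_fraction(chains, sim$genome)   # percent of genome that is ERV
#> [1] 2.507383
```

The divergence column is the gap-excluded p-distance between the 5' and
3' LTR; `age_mya = divergence / 0.004` under the default clock.  The
per-position over/under statistic describes the curves (positions are
autocorrelated); `over_under_by_erv()` is the calibrated test — here the
unbiased simulation (antisense bias 0.5) is correctly not rejected.

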