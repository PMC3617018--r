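---
title: "Detecting divergence in higher-order chromatin structure between species"
author: "chromdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting divergence in higher-order chromatin structure between species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdiverge)
```

## The problem

Mammalian genomes are organised into large domains of higher-order chromatin
structure — hundreds of kilobases to megabases of relatively "open"
(early-replicating, nuclear-interior, transcriptionally permissive) or
"closed" (late-replicating, lamina-associated, repressive) chromatin. Three
very different assays read out this organisation at a coarse grain:
replication timing (RT, log2 early/late signal), DamID lamina association
(LA, log2 Dam-fusion/Dam-only) and the first eigenvector of a Hi-C contact
matrix (the A/B compartment axis). Although each was designed to measure
something nominally different, all three correlate strongly along the
genome, and all are largely conserved between human and mouse.

`chromdiverge` asks the complementary question: **which orthologous regions
have changed?** Given many noisy structure tracks per species, it identifies
100 Kb regions whose mean structure differs between two species more than
the variability among datasets can explain, characterises how those regions
cluster along chromosomes, and tests where they sit (chromosome ends,
centromeres, arbitrary annotation sets) and what they contain (GC shifts,
genes, expression divergence).

Because the original input tracks are large external downloads, the package
carries a first-class synthetic-data module that generates two-species
studies with known ground truth. Every stage of the analysis is exercised,
and its operating characteristics measured, against that module.

## Data model

* **`GenomeLayout`** — ordered chromosome names/lengths with optional
  centromeres and acrocentric flags; the coordinate universe for binning,
  window construction and circular permutation.
* **`BinTrack`** — per-dataset values on fixed 100 Kb bins (0-based,
  half-open), with probe counts where the values were averaged from probes.
* **`StructureMatrix`** — orthologous region pairs × datasets, complete-case
  by construction; the single container the statistical machinery consumes.
* **`DivergenceResult`**, **clusters**, **`EnrichmentResult`** — per-region
  statistics with global FDR bookkeeping, maximal same-polarity runs with
  permutation p-values, and observed-vs-null enrichment summaries.

The sign convention is uniform: larger normalised value = more open. LA
tracks (where large means lamina-associated, i.e. closed) should be
sign-flipped at load time; RT and Hi-C eigenvalue tracks keep their native
sign, with the Hi-C eigenvector orientation assumed to follow the published
convention (positive = open compartment).

## From probes to an orthologous matrix

1. **`bin_probes()`** assigns probes to bins by midpoint (integer division)
   and averages them. Cells with fewer than `min_probes = 10` probes are
   discarded as unreliable. Terminal sub-bin chromosome remnants are never
   binned: a fixed-width average over a ragged remnant would not be
   comparable with the other bins.
2. **`collate_species()`** intersects datasets within a species. A region
   survives only if present in every dataset with coordinate overlap of at
   least 50% of the bin width; on identical grids this reduces to exact
   coordinate match plus a complete-case rule.
3. **`map_orthologs()`** pairs regions across species using a supplied
   interval orthology map annotated with both overlap fractions (such maps
   are produced upstream by reciprocal whole-genome alignment lift-over; the
   package deliberately does not re-derive them). A pair is retained when it
   is its own reciprocal best partner on both sides and both fractions reach
   the threshold (inclusive at exactly 50% — the natural reading of "at
   least"). Ties are broken deterministically: larger overlap in bp, then
   partner chromosome, then lower partner start. Unpaired regions are
   reported as putatively lineage-specific, never silently dropped.

## Quantile normalisation

`quantile_normalise()` forces every dataset column onto one common
distribution — the across-column mean of order statistics — so that RT, LA
and Hi-C values become directly comparable despite their different units and
dynamic ranges. Rank order within a column is untouched, hence all rank
statistics (Spearman correlations, rank-sum tests) are invariant under the
step. Tie handling matters across dialects and is therefore pinned down:
tied values receive the *mean of the reference entries their rank span
covers* (for a two-way tie at ranks 1–2, the mean of the two smallest
reference values). The implementation is a few lines in-package so this rule
is exact; the test suite cross-checks it against an established microarray
implementation on tie-free data, where all dialects agree.

Normalisation is applied jointly across both species' columns: a single
reference distribution describes every dataset, so between-species
differences in a region are differences in rank, not platform artefacts.

## The divergence statistic

For each region, species A's values `x_A` (one per dataset) are compared
with species B's `x_B` by a moderated unpaired difference statistic

```
d = (mean(x_A) - mean(x_B)) / (s + s0)
```

where `s` is the classical pooled standard error of the mean difference and
`s0` is a small exchangeability constant that prevents regions with tiny
`s` from dominating the tails. By default `s0` is the median of the
per-region `s` values; a percentile-grid alternative chooses the percentile
minimising the coefficient of variation of `|d|` dispersion across
`s`-quantile bands (`estimate_s0()`).

Significance comes from permutation of the species labels over dataset
columns, with the **same** relabelling applied to every region, preserving
the correlation structure among regions. Labels are drawn uniformly over
assignments preserving class sizes; when the number of distinct assignments
is at most 10,000 (e.g. `C(12, 6) = 924` for six datasets per species) the
space is enumerated exhaustively and the Monte-Carlo budget is irrelevant.

The FDR at a candidate cut pair is the **median**, over permutations, of
the number of permuted scores beyond the cuts, divided by the observed call
count. `call_divergence()` scans candidate cut pairs loosest-first —
asymmetric cuts located where the sorted observed scores depart from their
permutation-expected values by at least a threshold (the default), or a
simple symmetric `|d|` cutoff — and selects the loosest cuts meeting the
FDR target (default `2e-4`, chosen so that well under one false positive is
expected among hundreds of calls). Calls are necessarily bipolar: polarity
+1 means open in species A and closed in B, −1 the reverse. If no cut pair
meets the target the result carries zero calls and a warning flag rather
than an error. The sorted observed scores against their permutation
expectations (`expected_scores`) give the familiar Q-Q diagnostic: the null
bulk hugs the diagonal and genuine divergence departs in the tails.

## Clustering of divergent regions

`find_runs()` collects maximal runs of called bins that share polarity and
are exactly coordinate-adjacent; orthology coverage gaps break runs, and no
gap tolerance is applied — a conservative choice that understates cluster
sizes rather than bridging unrelated calls. `run_length_null()` shuffles
the per-bin labels (the full +1/−1/0 mix travels with the shuffle) among
each chromosome's bins, keeping coordinates fixed, and records the longest
run in each permuted genome; `p(n)` is the fraction of permuted genomes
containing a run of length ≥ n and is monotone non-increasing.

`call_clusters()` defaults to the operational "never seen" rule: a run is a
significant divergence cluster when no permuted genome produced a run that
long, with the p-value reported as the bound `1/n_perm` rather than zero.
With a numeric `alpha`, never-seen runs qualify when `1/n_perm <= alpha`.
A practical note on the null's geometry: with ~10% of bins divergent, runs
of 4 adjacent same-polarity bins still arise in a few percent of permuted
genomes, so at genome scale the never-seen threshold typically sits at runs
of 5–6 bins; only tracts at least that long are *detectable* as clusters,
and the recovery report (`evaluate_recovery()`) accounts for this.
Clustering is run separately in each species' coordinate frame and
`reconcile_clusters()` lists the clusters detected in both.

## Positional enrichment by circular permutation

A null for "where do divergent regions sit?" must preserve their observed
clustering, otherwise every test degenerates into a test of clustering.
`permutation_test()` therefore rotates all regions on each chromosome by
one uniform random offset, treating the chromosome as circular
(`circular_shift()`; intervals wrapping past the end are split, keeping
their identity). Interval lengths and pairwise spacings are conserved by
construction. Two statistics are provided: the number of regions
intersecting a feature set (≥1 bp, the default overlap notion; windows of
interest are built by `subtelomere_intervals()` / `centromere_intervals()`
following the arm conventions — acrocentric chromosomes contribute only
their distal end) and the median distance from region boundaries to the
nearest feature boundary. P-values follow the raw `n/n_perm` convention
with the qualifying direction inclusive of ties; the observed-inclusive
`(1+n)/(1+n_perm)` form is available via `add_one = TRUE`.

## Downstream association statistics

All standard tests are delegated to base R: Spearman correlation matrices
with average-linkage ordering on `1 − rho` distance (`correlation_matrix()`),
chi-squared chromosome-distribution tests flagging standardized residuals
beyond ±1.96 (`chrom_distribution_test()`), rank-sum contrasts of GC and
gene density by divergence class with per-class least-squares lines
(`gc_by_class()`, `density_compare()`; both per-100 Kb and per-Mb units are
emitted), expression divergence as `log2((RPKM_A + c)/(RPKM_B + c))` with
pseudocount `c = 0.01` recorded in the output (`expression_divergence()`),
and Fisher's exact test for regulatory-class enrichment with the
cross-product odds ratio plus a Haldane-corrected companion for degenerate
margins (`class_enrichment_fisher()`). Genes are assigned to regions by
start coordinate — deterministic and strand-agnostic, as the whole analysis
is. The "absolute" expression mode restricts the divergent classes to
regions whose mean normalised structure also crosses the open/closed
boundary (0 on the normalised scale) in both species, separating relative
from absolute compartment changes. `overlap_qc()` summarises orthology
overlap fractions per class — the control that called divergence does not
simply mark poorly aligned sequence.

## The synthetic-data module

The generator emulates the features the analysis relies on:

* **Compartment domains** come from a two-state Markov chain per chromosome
  (`gen_compartments()`). The parametrisation pins down two quantities a
  user actually cares about: the stationary open fraction `p_open` and the
  mean run length over all runs, `mean_domain_bins` (open runs are geometric
  with mean `2·m·p_open`, closed with mean `2·m·(1−p_open)`). This requires
  `2·m·min(p_open, 1−p_open) ≥ 1`; the boundary case is strict alternation,
  and i.i.d. states are not reachable within this parametrisation — a
  deliberate trade: the run-length semantics are what the clustering null
  cares about.
* **Divergent tracts** (`implant_divergence()`) flip the species-B latent
  state to the opposite of A inside tracts placed within constant-state runs
  of A, so each tract has one well-defined polarity; tracts are disjoint
  with a one-bin spacer so implanted runs cannot merge. An optional end bias
  places a fraction of tracts within a window of chromosome ends, emulating
  subtelomeric enrichment of divergence.
* **Structure values** (`gen_structure()`) are state mean ± 1 plus a
  dataset offset (sd 0.15) plus bin noise (sd 0.5 by default, making a state
  flip a 4-sigma effect) — reproducing the bimodal marginals and the
  strongly positive inter-dataset rank correlations seen in real RT/LA/Hi-C
  panels.
* **Probes** (`gen_probes()`) scatter Poisson-many probes (mean 25)
  uniformly within bins with small probe noise, so binning recovers the bin
  values and the 10-probe filter has teeth.
* **Orthology** (`gen_orthology()`) derives the B genome as a
  block-rearranged copy of A and emits the pair map with overlap fractions,
  unmappable bins, sub-threshold decoys and non-reciprocal secondary
  candidates, each pair carrying a ground-truth keep flag computed by an
  independent generator-side rule.
* **GC, genes, expression, regulatory flags** are tied to the latent state
  and to the implanted tracts with controlled effect sizes (target Spearman
  for GC, Poisson rates by state, a log2-fold-change shift of ±1 inside
  tracts, a regulatory-divergence odds ratio of 2). The expression baseline
  shift defaults to 0: any overall offset seen in a real inter-species
  comparison is a property of that dataset pair, not of the model.

What the module does **not** emulate: platform-specific distribution
shapes, cell-type heterogeneity, sequence-driven mappability structure, raw
microarray or sequencing data, or Hi-C contact matrices (eigenvalue tracks
are consumed as tracks). Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated generative
assumptions — not fidelity to any particular published platform.

## Reference study conditions and problem sizes

The package's reference configuration (`pipeline_config()` defaults, used
by the acceptance script) simulates 8 chromosomes averaging 62.5 Mb —
about 5,000 orthologous 100 Kb bins — with 6 datasets per species, ~10% of
bins inside 4–8-bin divergent tracts, and half the tracts within 5 Mb of
chromosome ends. Permutation budgets in routine runs are 10,000 for
divergence (superseded by exhaustive enumeration of the 924 label splits),
and 2,000 each for the cluster and enrichment nulls; the published-scale
defaults (100,000 / 10,000 / 10,000) remain available in the config. Unit
tests use smaller genomes (hundreds to low thousands of bins) chosen so the
whole suite exercises every stage, including three full-scale recovery
runs, in a few minutes.

## Numerical and design choices

* Inclusive thresholds (`>=`) wherever a rule says "at least"; all
  reciprocal-best ties broken deterministically.
* Zero pooled standard errors are tolerated whenever `s0 > 0`; with a
  user-forced `s0 = 0` they raise an error rather than emit infinities.
* "Never seen" permutation p-values are reported as the bound `1/n_perm`,
  never as 0, and comparisons use the bound.
* The FDR numerator is the *median* permuted exceedance count (not the
  mean), making single wild permutations (e.g. the identity split, which is
  part of the exhaustive space) harmless.
* Per-stage RNG streams are derived from one master seed by stage name
  (`stage_seed()`), so changing one stage's draw count never perturbs
  another stage.
* Degenerate inputs (empty classes, missing centromeres, zero-bin
  chromosomes, zero calls) are flagged or skipped with warnings, never
  silently dropped.

## Known limitations

* Exactly two species; no multi-species contrasts.
* No gap-tolerant or HMM segmentation of divergence clusters — a missed
  interior bin splits a cluster.
* The permutation FDR is conservative when a large fraction of regions is
  genuinely divergent (permuted splits mix the two species' signals and
  inflate the null tails); at very stringent targets this trades a little
  sensitivity for near-zero false discovery.
* Functional-annotation enrichment (GO/DAVID-style) is out of scope; the
  generic two-class Fisher test is the provided substitute.
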