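# chromdiverge

Comparative analysis of higher-order chromatin structure between two
species. Given many noisy genome-wide structure tracks per species —
replication timing (log2 early/late), DamID lamina association
(log2 Dam-fusion/Dam-only), Hi-C A/B compartment eigenvalues —
`chromdiverge` identifies orthologous 100 Kb regions whose chromatin
structure has diverged, characterises how divergent regions cluster along
chromosomes, tests their positional enrichment, and relates them to GC
content, gene density and expression divergence.

It is aimed at comparative and regulatory genomicists who have per-species
binned or probe-level structure tracks plus an interval orthology map, and
want calibrated, permutation-based divergence calls rather than ad-hoc
thresholding.

## The method in brief

1. **Binning and orthology.** Probe tracks are averaged into consecutive
   non-overlapping 100 Kb bins (bins with < 10 probes discarded), collated
   within species (≥ 50% coordinate overlap across datasets), and paired
   across species by reciprocal best overlap (both fractions ≥ 50%);
   unpaired regions are reported as lineage-specific.
2. **Normalisation.** Joint quantile normalisation forces every dataset
   onto the common mean-of-order-statistics distribution, preserving ranks.
3. **Divergence calls.** Each region's species contrast is scored with a
   moderated unpaired statistic, d = (mean_A − mean_B)/(s + s0), where s is
   the pooled standard error and s0 an exchangeability constant (median of
   the per-region s by default). Global permutations of the species labels
   over dataset columns (enumerated exhaustively when the label space is
   small) give the null; the FDR at a cut pair is the median permuted
   exceedance count over the observed call count, and the loosest cuts
   meeting the target (default 2e-4) are selected. Calls are bipolar:
   +1 = open in species A / closed in B, −1 the reverse.
4. **Clusters.** Maximal same-polarity runs of exactly adjacent called bins
   are assessed against a within-chromosome label-shuffling null; runs
   never seen in the permuted genomes are significant divergence clusters
   (p reported as the bound 1/n_perm).
5. **Enrichment.** Circular permutation (rigid random rotation per
   chromosome, preserving the observed clustering) tests enrichment or
   depletion of divergent regions in subtelomeric/centromeric windows or
   any interval set, and boundary-distance association with domain sets.
6. **Associations.** Spearman correlation structure of all datasets,
   chi-squared chromosome distribution with standardized residuals, GC and
   gene-density contrasts by divergence class, expression divergence
   (log2 RPKM ratios) in relative and absolute modes, and Fisher's exact
   test for regulatory-class enrichment.

A synthetic-data module generates full two-species studies with known
ground truth (compartment domains, implanted divergent tracts, probes,
orthology maps with decoys, GC, genes, expression), so the entire pipeline
runs and is testable with no external data.

## Worked example

Simulate a small two-species study (four chromosomes, six datasets per
species, twenty implanted divergent tracts, half of them near chromosome
ends) and run the full pipeline:

```r
library(chromdiverge)

cfg <- pipeline_config(seed = 7L,
  simulate = list(n_chrom = 4L, mean_len = 3e7, n_tracts = 20L,
                  end_bias_frac = 0.5),
  divergence = list(n_perm = 5000L),
  cluster = list(n_perm = 2000L),
  enrichment = list(n_perm = 1000L, windows = 5e6))
bundle <- run_pipeline(cfg)

print(bundle$divergence)
#> DivergenceResult: 109/1078 regions called divergent (10.11%)
#>   s0 = 0.2841, cuts [-2.19, 2.56], FDR target 0.0002 achieved 0, exhaustive 924 permutations
```

109 of 1,078 orthologous bins (10.1%) are called divergent: their moderated
statistic falls beyond the cuts at which the median permuted exceedance
count is zero, so the achieved FDR estimate is 0 at the 2e-4 target. With
six datasets per species the 924 distinct label assignments were enumerated
exhaustively.

```r
print(bundle$enrichment$subtelomere_5Mb)
#> EnrichmentResult [overlap_count]: observed 75 vs null mean 39.77 (1000 perms)
#>   p_enrich = 0.002, p_deplete = 0.999
```

75 divergent bins fall within 5 Mb of a chromosome end versus 39.8 expected
under circular permutation — the implanted subtelomeric bias is detected at
p = 0.002.

```r
sig <- bundle$clusters_A[bundle$clusters_A$significant, ]
head(sig[, c("chrom", "start", "end", "length_bins", "polarity", "p_value")], 3)
#>    chrom    start      end length_bins polarity p_value
#> 8  chrA1 37500000 38300000           8       -1   5e-04
#> 10 chrA2  2100000  2600000           5       -1   5e-04
#> 11 chrA2  3900000  4600000           7        1   5e-04
```

Runs of 5–8 adjacent same-polarity bins were never seen in 2,000 permuted
genomes (p < 1/2000 = 5e-4) and are reported as divergence clusters. The
bundled ground truth quantifies recovery:

```r
str(bundle$recovery[c("sensitivity", "fdp")])
#> List of 2
#>  $ sensitivity: num 0.965
#>  $ fdp        : num 0
```

96.5% of implanted divergent bins are called with the correct polarity and
no non-divergent bin is called (realised false discovery proportion 0).

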