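# k4redist

Analysis of genome-wide **H3K4me3 redistribution** in relation to infant
growth trajectories. In stunted children (height-for-age z-score, HAZ,
below −2 at one year) the H3K4me3 mark is not lost but *redistributed*:
average signal at transcription start sites falls while a broad low-level
gain spreads across non-peak regions, and the change tracks ΔHAZ — the
change in HAZ from birth to one year. Standard count normalization
assumes no global shift and silently absorbs exactly this signal, so the
package implements the two devices that expose it, plus the surrounding
analyses:

* an **exponential background model** for 150-bp binned read counts: the
  histogram of bins over read count is log-linear at low counts,
  `log N_k = intercept − λ·k`; fitting that line (upper bound of the fit
  range optimized per dataset by R²) and capping the fitted curve at the
  observed histogram partitions each library into
  `background_reads = Σ_k k·min(N_k, N̂_k)` versus signal in peaks;
* **size factors** by total counts, median-of-ratios, exogenous spike-in
  reads, or the fitted background depth (`size_factors_*`);
* per-feature **negative-binomial regression** of peak/transcript counts
  on ΔHAZ with sex adjustment, size-factor offsets, method-of-moments
  dispersion and a t-referenced Wald test with BH-FDR
  (`fit_feature_models`), plus PCA and Pearson/Ward clustering;
* strand-aware **TSS proximity, metagene profiles and peak-set overlap**
  (`distance_to_nearest_tss`, `metagene_profile`, `peak_set_overlap`);
* **overlap/shift statistics**: exact upper-tail hypergeometric tests,
  exact/approximate Wilcoxon rank-sum, and a signed-rank test for a
  global ERCC spike-in shift;
* a **synthetic-cohort generator** (`simulate_cohort`,
  `simulate_ercc_rnaseq`) emulating the redistribution phenotype —
  geometric background, TSS-localized peaks, a mistargeted fraction
  `m = clip(m₀ − s·ΔHAZ, 0, 1)` under a conserved total read budget, and
  spike-ins independent of ΔHAZ — because the cohort data themselves are
  controlled-access.

## Worked example

```r
library(k4redist)

genome  <- genome_model()                      # 2 x 7.5 Mb, 150-bp bins
design  <- cohort_design(24, seed = 1)         # HAZ trajectories, sex
params  <- redistribution_params()             # mistarget_slope = 0.1
cohort  <- simulate_cohort(genome, design, params, spikein_params())

bg <- fit_cohort_background(cohort$coverage)
partition_trend(bg, design$delta_haz, "background_fraction")
#> k4_trend (background_fraction): slope -0.0800 +/- 0.0011 per dHAZ unit (n = 24)

m  <- counts_in_peaks(cohort$coverage, cohort$peaks)
sf <- size_factors_spikein(cohort$metadata$spikein_reads)
res <- fit_feature_models(m, cohort$metadata, sf)
median(res$log2fc_per_dhaz[cohort$peaks$at_tss])
#> [1] 0.2345689
```

The background-plus-mistargeted read fraction falls by 0.08 per ΔHAZ unit
(signal moves *into* peaks as growth improves), and with spike-in size
factors the TSS peaks show a positive median slope of ≈0.23 log2 units
per ΔHAZ unit. Under median-of-ratios normalization the same cohort gives
a median TSS-peak slope of ≈0.000 — the global shift is absorbed into the
size factors, which is precisely why the spike-in route matters. For the
overlap arithmetic used on gene lists:

```r
hypergeometric_overlap(n_a = 829, n_b = NA, n_overlap = 658, n_universe = NA)
#> k4_overlap: 658 of 829 (79.4%) (no universe: p not computed)
```

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on the synthetic
cohort and write tables to `results/tables/` (figures go to
`scratch/figures/`):

```sh
Rscript analysis/01_simulate.R        # cohort files + metadata
Rscript analysis/02_background_fit.R  # per-sample fits, partition trend
Rscript analysis/03_metagene.R        # TSS profiles by group, rank tests
Rscript analysis/04_differential.R    # size factors, NB regression, PCA,
                                      # clustering, TSS proximity of hits
Rscript analysis/05_rnaseq_ercc.R     # ERCC global-shift test
Rscript analysis/06_overlap_stats.R   # hypergeometric overlap summaries
```

Each stage regenerates the seeded cohort deterministically, so stages can
be run independently and reruns are bit-identical.

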