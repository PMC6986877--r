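# gliEnhancers

Classification of Hedgehog-responsive GLI enhancers from differential
chromatin profiling.

## The problem

GLI transcription factors act as repressors in the absence of Hedgehog (HH)
ligand and as activators in its presence. At GLI binding regions (GBRs),
the active-enhancer mark H3K27ac can respond to HH signalling in three
qualitatively different ways when the two conditions — wild type (active HH)
and a HH-deficient mutant — are compared:

- **Stable**: H3K27ac retained in both conditions;
- **HH-sensitive**: H3K27ac significantly reduced, but still detectable,
  without HH;
- **HH-dependent**: H3K27ac enrichment completely absent without HH.

This package implements the full analysis that produces and characterises
these classes, for anyone who has per-condition ChIP-seq/ATAC-seq region
sets and read counts (or wants to study the pipeline's behaviour on
simulated data with planted ground truth).

## The statistics at the core

Per-region counts are depth-normalised and variance-stabilised as
`log2(count * D / library_size + 1)` with `D` a reference depth. The
wild-type vs mutant contrast is tested with an empirical-Bayes moderated
t-statistic: the pooled per-region variance `s_g^2` (on `d_g` df) is shrunk
toward a prior,

    s~^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g),
    t~   = (mean_A - mean_B) / (s~ * sqrt(1/n_A + 1/n_B)),  df = d0 + d_g,

with `(d0, s0^2)` estimated by closed-form moment matching of the log sample
variances (digamma/trigamma equations). Benjamini–Hochberg adjustment gives
q-values; peak presence per condition comes from a fixed-window Poisson peak
caller (a documented simplified stand-in — real peak calls can be supplied
as BED). Classification applies, in precedence order: no wild-type
acetylation → `non_acetylated`; all overlapping acetylation vanished in the
mutant → `hh_dependent`; any overlapping region with `q < 0.05` and positive
log2 fold change → `hh_sensitive`; otherwise `stable`.

Around the classifier: Fisher's exact and two-proportion tests for
promoter-proximity and motif-presence contrasts, Wilcoxon rank-sum tests for
accessibility, permutation tests (region counts near target-gene TSS windows
against uniformly resampled gene sets), and log-odds PWM scanning of region
sequences on both strands.

## Worked example

Two in-paper statistics recomputed from printed class counts:

```r
library(gliEnhancers)

# 3,544/5,715 promoter-proximal Stable vs 91/349 promoter-proximal
# HH-responsive GBRs, two-sided Fisher's exact test
fisher_exact_2x2(3544, 2171, 91, 258)
#> [1] 9.094955e-40

# GLI-motif presence, HH-sensitive (57.4% of 148) vs Stable (39.5% of 5,715),
# one-sided two-proportion test with continuity correction
two_proportion_test(85, 148, 2257, 5715, "greater")
#> [1] 8.002234e-06
```

The end-to-end pipeline on the bundled synthetic-data generator (toy genome,
planted GBR classes, negative-binomial counts, planted GLI motifs):

```r
cfg <- pipeline_config(outdir = "demo_run", seed = 1)
run_pipeline("all", cfg)
cls <- read.delim("demo_run/gbr_classification.tsv")
class(cls) <- c("gbr_class", "data.frame")
print(cls)
#> GBR classification: 320 regions (320 acetylated)
#>   stable            202  (63.1% of acetylated)
#>   hh_sensitive       58  (18.1% of acetylated)
#>   hh_dependent       60  (18.8% of acetylated)
#>   non_acetylated      0
```

The run directory also contains `differential_acetylation.tsv` (per-region
log2 fold changes, moderated t, q-values, peak types),
`tss_enrichment.json` (the responsive classes reject the permutation null at
`p_plus_one = 1/1001` with 1000 permutations), `motif_report.json`
(per-class motif presence/quantity/quality with one-sided tests) and
`accessibility_tests.tsv`. Ground truth for every planted region is in
`demo_run/sim/truth.tsv`; with the default configuration the pipeline
recovers ≥95% of planted labels in every class. The same stages are
available from a shell via `Rscript inst/scripts/gli-pipeline.R --step all
--outdir demo_run --seed 1`.

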