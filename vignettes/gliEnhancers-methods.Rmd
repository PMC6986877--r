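---
title: "Classifying Hedgehog-responsive GLI enhancers: models, parameters and design choices"
author: "gliEnhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Hedgehog-responsive GLI enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliEnhancers)
```

## The analysis

GLI transcription factors repress their target enhancers when Hedgehog (HH)
ligand is absent. Comparing the active-enhancer mark H3K27ac between a
wild-type limb bud (HH active) and a HH-deficient mutant partitions GLI
binding regions (GBRs) into classes: **Stable** (acetylation retained),
**HH-sensitive** (significantly reduced) and **HH-dependent** (no called
enrichment at all in the mutant). The package implements this pipeline as
composable stages: interval arithmetic and BED/TSV/FASTA I/O; per-condition
peak calling; counting and normalisation; a moderated-t differential test;
the three-way classifier; permutation enrichment near target-gene TSSs; PWM
motif statistics; and accessibility comparisons. A seeded synthetic-data
generator with planted ground truth exercises every stage.

## Coordinates and interval semantics

All coordinates are 0-based half-open (the BED convention), everywhere.
Overlap means at least one shared base; adjacent intervals (`end == start`)
do not overlap and are not merged. A fractional-overlap threshold is
deliberately not the default — "intersect" is interpreted as any-overlap,
the simplest defensible rule. Promoter windows are strand-aware: for a
plus-strand TSS `t` the window is `[t - upstream, t + downstream)`, for a
minus-strand gene its coordinate mirror; the one-base asymmetry of where the
TSS base itself falls is immaterial at kilobase scale. A strand-ignorant
mode (`stranded = FALSE`) exists because region-to-TSS analyses are
sometimes done unstranded; strand-aware is the default. Default windows are
2 kb upstream / 1 kb downstream for promoter proximity and enrichment, and
5 kb upstream / 2.5 kb downstream for calling a TSS CpG-island-associated.

## Normalisation and the moderated t

Counts are normalised as `log2(count * D / library_size + 1)` with reference
depth `D` defaulting to the median library size (the scaling target is
otherwise arbitrary). The pseudo-count of 1 makes zero counts map to 0 and
stabilises the log at low coverage.

The two-condition test is the empirical-Bayes moderated t: per region the
pooled variance \(s_g^2\) on \(d_g = n_1 + n_2 - 2\) df is shrunk toward a
prior \(s_0^2\) carrying \(d_0\) prior df,
\(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\), and
\(\tilde t = \Delta \bar y / (\tilde s \sqrt{1/n_1 + 1/n_2})\) is referred
to \(t_{d_0 + d_g}\). The prior is estimated by closed-form moment matching
of the log variances: with \(z_g = \log s_g^2\),
\(e_g = z_g - \psi(d_g/2) + \log(d_g/2)\), the trigamma equation
\(\psi'(d_0/2) = \widehat{\mathrm{Var}}(e) - \psi'(d_g/2)\) is solved by a
Newton inversion of the trigamma function. When the spread of log variances
is no larger than sampling alone explains, \(d_0\) is treated as infinite
(full shrinkage) and a notice is emitted. With \(d_0 = 0\) the statistic is
the classical pooled t; both limits are property-tested, and the whole
estimator is cross-checked against an independent reference implementation
in the test suite. Zero sample variances (possible with tiny counts) are
excluded from prior estimation and shrink fully to \(s_0^2\).

Only two-group contrasts are supported; the analyses this package targets
are condition-vs-condition or sample-vs-input comparisons, not general
design matrices.

## The simplified peak caller

The fixed-window caller tiles the genome with non-overlapping windows
(default 200 bp), tests each window's count against the genome-wide
background rate with an upper-tail Poisson test, adjusts across all windows
by Benjamini–Hochberg, and merges runs of consecutive significant windows
(q < 0.05 by default). It deliberately omits local background models,
fragment-length estimation and duplicate handling; it exists so the
pipeline runs end-to-end on simplified point reads, and externally produced
peak calls can be supplied as BED at every entry point that takes peaks.
The genome-wide background rate plays the role of the input control; the
synthetic generator correspondingly does not emit input read files.

## Classification rules

Per GBR, over the differential results of the wild-type-present acetylation
regions overlapping it, in precedence order:

1. none → `non_acetylated`;
2. all have `peak_type == "a_only"` (no mutant peak) → `hh_dependent`;
3. any with `q < fdr` and positive log2 fold change → `hh_sensitive`;
4. otherwise → `stable`.

"Complete absence" is read conservatively: a GBR is `hh_dependent` only if
*every* overlapping wild-type acetylation region lost its mutant peak; a
retained but significantly reduced region demotes it to `hh_sensitive`.
"HH-responsive" always denotes `hh_sensitive` and `hh_dependent` pooled.
Absence-vs-reduction is decided from peak presence, not from the magnitude
of the fold change, so the two-tier distinction is robust to how far a
vanished region's count happens to fall. Co-mark annotations (H3K4me1/2,
ATAC, H3K27me3) are plain any-overlap booleans.

Accessibility comparisons use one-sided Wilcoxon rank-sum tests with
direction chosen per measure: for wild-type signal, "stable more
accessible"; for the per-region log2 condition ratio (A − B), "responsive
loses more than stable" — the directions in which the underlying biology
(restricted accessibility of responsive enhancers, further compaction under
constitutive repression) predicts a shift.

## Permutation enrichment

The TSS enrichment statistic counts *regions* overlapping at least one
promoter window of the target gene set (counting hit *genes* instead is an
option; region counting was chosen as the more natural measure of how much
of a region set is promoter-associated). The null redraws gene sets of the
same size uniformly without replacement. Both `p_plain = #{null ≥ obs}/B`
(which can be exactly 0) and the bias-corrected
`p_plus_one = (1 + #{null ≥ obs})/(1 + B)` are reported; `p_plus_one` is
recommended, since a permutation p of 0 understates the attainable
resolution `1/(B+1)`. The neighbour-clustering test repositions each query
region uniformly on its own chromosome with length preserved; matching GC
or other covariates in the null is out of scope. Whether the random gene
sets should be matched on expression or chromosome is an open question in
the underlying design; uniform sampling is implemented and documented.

## Motif statistics

PWMs are loaded from JASPAR-style text, converted to probabilities with a
pseudocount (default 0.25) and scored as log2 odds against a background
(default uniform). Scanning is exhaustive over both strands; windows
containing `N` are skipped; reverse-strand hits are reported in
forward-strand coordinates. Per region: `has_motif` (any hit at the
threshold), `quantity` (hit count) and `quality` (mean hit score over that
region's hits; a `max` mode exists because the aggregation convention is
genuinely ambiguous — mean is the default). Class comparisons test presence
with the one-sided continuity-corrected two-proportion test and
quantity/quality with one-sided Wilcoxon tests restricted to
motif-containing regions.

The bundled GLI-like matrix is synthetic, built from the canonical
GACCACCCA consensus (count 10 at the consensus base per position before
pseudocounts, max score ≈ 17.1 bits); it is for synthetic data and testing,
and real analyses should supply an experimentally derived matrix. The
general scanning default of 7 bits admits single-mismatch sites; on 400 bp
of random sequence those occur at ≈ 0.08 expected hits per region
(~780 windows × 1.1 × 10⁻⁴), which would inflate presence fractions by
several points. The pipeline therefore scans at 12 bits — the same strength
the generator plants — so that presence measured by scanning estimates the
planting rate essentially without background contamination.

## The synthetic-data generator

The generator emulates the study design the pipeline addresses: two
conditions, two replicates each (pooled-embryo ChIP replicates), a toy
two-chromosome genome, annotated genes with CpG islands, planted GBRs of
the three classes, and negative-binomial read counts. Its defaults define
the package's standard test conditions:

- **Geometry**: 2 × 3 Mb chromosomes; 240 genes; 15% designated HH targets;
  GBRs 400 bp, placed with ≥1 kb gaps so that window-quantised peaks of
  neighbouring regions never merge. The genome is sized so the placement
  constraints (promoter windows, gaps, the non-GBR bulk) leave comfortable
  capacity.
- **Classes**: 200 stable / 60 sensitive / 60 dependent — the published
  ~6:1 stable:responsive imbalance at desk scale. Promoter placement
  probabilities 0.62 / 0.26 / 0.26 mirror the published promoter-proximal
  fractions; promoter-placed responsive GBRs use target-gene promoters
  (responsive enhancers concentrate at HH targets), stable ones any gene.
- **Non-GBR acetylation bulk**: 600 stable plus 30 responsive non-GLI
  regions, the latter clustered within 50 kb of responsive GBRs. In real
  data the changing regions are a few percent of a ~60,000-peak landscape;
  without this bulk, planted changes were a third of all regions and
  library-size normalisation showed textbook composition bias (stable
  regions acquired a spurious −0.36 log2 shift). The bulk restores a
  realistic composition, and the clustered responsive subset feeds the
  neighbour-enrichment analysis.
- **Signal**: baseline 150 reads/region/replicate, background 20,000
  scattered reads/sample, per-sample depth factors (1, 1.15, 0.9, 1.05).
  Sensitive regions drop 1.5 log2 units in the mutant; dependent regions
  drop to background. NB dispersion is 0.025: each replicate in the
  emulated design pools 6–8 embryos, which suppresses biological
  variability, and a power analysis at the 1.5 log2 drop with n = 2
  replicates (moderated t on ≈ 7 total df — the prior df stays moderate
  because near-zero mutant counts of dependent regions spread the log
  variances — against a BH cutoff near 0.008) shows dispersion must be
  ≲ 0.03 for the classifier to recover the sensitive class at the intended
  ≥ 80% rate. 0.025 keeps that power with margin while leaving the
  separation far from trivial (sensitive recovery runs in the low 90s%, not
  at 100%).
- **Motifs**: planted with probabilities 0.70 / 0.57 / 0.40
  (dependent / sensitive / stable — the published presence fractions),
  one instance per selected GBR, sampled from the PWM conditional on
  scoring ≥ 12 bits, inserted in place (no indels) on a random strand.
- **Accessibility**: stable GBRs at mean 120 reads in both conditions;
  responsive GBRs 1.5 log2 lower in wild type and a further 0.5 (sensitive)
  or 1.5 (dependent) log2 lower in the mutant, mirroring restricted and
  further-compacted accessibility.

What the generator does **not** emulate: fragment-level reads, GC and
mappability bias, duplicate reads, local background structure, diploid
genomes, and real motif background composition. Passing recovery tests on
this generator therefore demonstrates the pipeline's statistical and
logical correctness under a faithful stochastic model of the design — not
robustness to alignment artefacts or sequence-composition confounders of
real genomes.

## Problem sizes and numerical choices

The default bundle (950 signal regions, ~1.3 M reads over 16 read files)
runs end-to-end in well under a minute; the test suite uses a reduced
configuration for pipeline mechanics and the default bundle for recovery
and calibration checks. Calibration of the permutation test uses
`n_perm = 199`, making rejection at `p_plus_one ≤ 0.05` have exact nominal
level 10/200; its null geometry (120 regions, 60 genes, 9-gene targets)
gives the count statistic many distinct values, keeping discreteness
conservatism small. Fisher's exact test is computed from log-space
hypergeometric point probabilities with the conventional `≤ observed ×
(1 + 10⁻⁷)` tie tolerance; the doubling rule is available as an option.
Degenerate inputs are handled explicitly: empty region sets propagate as
empty results, zero-variance regions shrink fully to the prior, zero reads
yield an empty peak list with a warning, and a pooled proportion of 0 or 1
returns p = 1.

## Known limitations

- The peak caller is a stand-in; for real data, import MACS2/CisGenome
  calls as BED.
- One TSS per gene is assumed; multi-isoform promoter selection is out of
  scope.
- The classifier consumes peak presence as evidence of "complete absence";
  detection sensitivity of the underlying assay (e.g. low-input ChIP) is a
  data property the classifier does not model.
- Permutation nulls are uniform — no matching on expression, GC or
  chromatin context.
- Motif quality scores are in bits against the supplied background; they
  are comparable between classes scanned with the same matrix, not across
  matrices.
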