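---
title: "Quantitative ChIP-seq comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ChIP-seq comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmetrics)
```

## The problem

ChIP-seq read counts are only proportional to chromatin occupancy *within*
one library. Comparing a histone mark between two conditions therefore
requires a between-sample scaling, and the usual choice — equalizing total
mapped reads — silently assumes that total genome-wide occupancy is the
same in both conditions. For a mark like H2Bub1 (histone H2B
monoubiquitylated on its C-terminal tail), that assumption fails in the
most interesting situations: when the deubiquitylation machinery is
removed, H2Bub1 rises globally over transcribed gene bodies, and
total-read scaling would normalize the effect away.

`chipmetrics` implements the quantitative comparison strategy built
around that failure mode:

1. **Background-anchored size factors.** Large intergenic regions, far
   from any annotated gene, carry only nonspecific background pull-down.
   Their read counts scale with sequencing depth but not with the genic
   signal, so per-sample size factors estimated from an
   intergenic-region count matrix recover the depth differences without
   being contaminated by the biology. The estimator is the classical
   median-of-ratios: for region $i$ with counts $k_{ij}$ in sample $j$,
   $$ s_j = \operatorname*{median}_{i\,:\,k_{i\cdot}>0}
      \frac{k_{ij}}{\left(\prod_{v} k_{iv}\right)^{1/m}}, $$
   computed over regions with positive counts in every sample
   (`size_factors_intergenic()`). For antibodies whose global occupancy
   is *not* expected to change (total Pol II, Pol II Ser2P),
   total-mapped-read factors are appropriate and provided
   (`size_factors_total()`, centered on the geometric mean so no sample
   is privileged).
2. **Occupancy density.** Per-region signal is summarized as
   $$ \text{density} =
      \frac{\text{reads in region}/\text{region length (bp)}}
           {s_j \times 10^{-8}}, $$
   a depth-corrected reads-per-bp rate on a convenient scale
   (`density_value()`, `density_table()`). Condition-level changes are
   reported as the ratio of per-gene density medians
   (`fold_change_summary()`) with a two-sided Wilcoxon rank-sum test
   with continuity correction on the per-gene distributions
   (`rank_sum_test()`).
3. **Fixed-bin average profiles.** Metagene profiles divide every gene
   body into 160 equal bins regardless of length, flanked by 20 fixed
   250-bp bins on each side (200 bins total); TSS-centered profiles use
   a 2-kb window in 10-bp bins. K-means clustering of the per-gene bin
   matrix separates signal archetypes (`profile_matrix()`,
   `cluster_profiles()`).
4. **Traveling ratio.** Promoter-proximal Pol II pausing is quantified
   per gene as the ratio of per-bp signal in the TSS window
   ($-100..+300$ bp) to that in a fixed early-body window
   ($+300..+2000$ bp); cohort distributions are compared via their
   ECDFs with the two-sample Kolmogorov–Smirnov statistic
   (`traveling_ratio()`, `ks_two_sample()`).
5. **DE bookkeeping.** Differential-expression results arrive as a
   table (gene id, base-median normalized count, log2 fold change,
   adjusted p); the package applies the standard thresholds
   ($p_{\text{adj}} \le 0.05$, $|\log_2 FC| \ge 1$), cumulative
   fold-change bins, set overlaps and cross-study correlation
   (`classify_de()`, `fold_bin_counts()`, `overlap_counts()`,
   `log2fc_correlation()`). The DE model itself is never refit here.

## Coordinate and counting conventions

All internal coordinates are 0-based, half-open (BED-native); GTF input
is converted at the file boundary. A tag is a stranded 5' position
(`start` for `+`, `end - 1` for `-`). For coverage-based computations a
tag is extended to a fixed fragment length (default 200 bp) in the read
direction.

Two counting modes exist, and they are used deliberately:

* **Densities** count a read as "in" a region when its extended
  interval overlaps the region by at least 1 bp (`overlap` mode). This
  mirrors how fragments are attributed to gene bodies.
* **Profiles** use per-bp coverage (`coverage` mode), averaged within
  each bin, so bins of unequal width (fractional body bins vs 250-bp
  flank bins) remain directly comparable. The bin aggregation is exact:
  cumulative per-bp coverage is interpolated at real-valued bin edges,
  so the identity
  $\sum_b \text{value}_b \times \text{width}_b \times s_j =
  \text{total coverage in the window}$ holds to floating-point
  precision, and a uniform signal produces an exactly constant 200-bin
  vector.
* **Traveling ratios** count unextended 5' positions. The two windows
  are short (400 and 1700 bp) and adjacent; extension-based overlap
  counting would attribute boundary-straddling reads to both windows
  and inflate the short window systematically (a uniform signal would
  yield TR ≈ 1.3 rather than 1). With 5'-position counting a uniform
  signal gives exactly 1, and the per-gene ratio is invariant to
  library depth because the size factor cancels.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `extension_bp` | 200 | bp | typical sonicated-fragment length for 50-bp single-end tags |
| `scale_const` | 1e-8 | — | places gene-body densities on a convenient absolute scale |
| `min_reads` | 1 | reads | genes with no signal in any sample are uninformative for fold changes |
| expression floor | 10 | normalized reads / kb of median transcript length | separates expressed from silent genes (strict inequality) |
| TR expression floor | 100 | normalized reads / kb | pausing estimates need dense promoter coverage; strict |
| TR length floor | 1000 | bp | the body window must not be dominated by the TSS window; strict |
| neighbor window | 5000 | bp | flanking signal bleed between close gene units; both members of a close pair are removed (symmetric exclusion) |
| intergenic `min_len_bp` | 100000 | bp | long regions average out local artifacts on a mammalian genome |
| intergenic `gene_buffer_bp` | 10000 | bp | "far from genes" made explicit and configurable |
| body bins / flank bins | 160 / 20×250 bp | — | fixed-bin metagene scheme |
| TSS window / bin | 2000 / 10 | bp | promoter-proximal peak localization |

Thresholds phrased as "over" or "more than" are strict inequalities;
the DE thresholds ($\le$, $\ge$) are boundary-inclusive.

## What the synthetic generator emulates

`simulate_genome()`, `sim_truth()` and `simulate_tags()` produce a toy
single-chromosome genome and seeded tag libraries with the structural
features the analysis measures:

* a promoter-proximal Pol II peak, Gaussian around TSS +60 bp (sd 50
  bp), on top of a uniform gene-body rate, with a per-gene planted
  promoter:body ratio;
* an H2Bub1 gene-body signal: a plateau over the body with a smooth
  onset and a Gaussian bump peaking at TSS +300 bp, multiplied in KO
  samples by the per-gene planted fold;
* a Ser2P-like signal rising toward the TES, with a TES accumulation in
  a configurable fraction of genes (the basis for two-cluster
  separation);
* uniform intergenic background (default 0.001 fragments/bp at depth 1)
  and per-sample depth factors.

Fragment centers are drawn from thinned Poisson processes; the 5' tag
positions are placed so that extension to the fragment length
reconstructs the fragment, and each library is deterministic given the
truth seed, sample and mark.

Defaults were chosen once as round numbers on the scale of real
mESC/MEF libraries: a median gene-body rate of 0.05 fragments/bp with
log-normal gene-to-gene spread (sdlog 0.3), a background 50-fold lower,
300 genes of 2–8 kb separated by 20–40 kb gaps (a ~10-Mb genome).
Because the toy genome is roughly 1/250 of a mouse genome, the
intergenic selection in simulation-scale analyses uses a
correspondingly scaled length floor (10 kb, with a 5-kb gene buffer)
instead of the 100-kb floor appropriate for a full genome; the
estimator is identical.

What the generator does **not** emulate: mappability and sequence
composition, GC bias, copy-number variation, antibody efficiency
differences, replicate structure, or peak shape heterogeneity. Passing
the recovery tests therefore demonstrates that the *estimators* are
unbiased and depth-invariant under the stated signal model, not that
any particular biological dataset satisfies that model.

## Numerical and design choices

* **Median-of-ratios handling of zeros.** Regions with a zero count in
  any sample are dropped before forming ratios (their geometric mean is
  zero); at least one all-positive region is required. Medians of
  even-length ratio vectors are the mean of the two central values.
* **Centering and re-anchoring.** Median-of-ratios factors are centered
  through the per-region geometric means, which ties every factor to
  every sample. Consequently, duplicating one library's reads changes
  *all* factors (by construction their product over two samples with
  constant ratios is 1). When absolute densities must be compared
  across re-estimations, `rescale_factors()` re-anchors the set so a
  chosen reference sample has factor 1; fold changes and rank-based
  statistics are invariant to the centering either way.
* **Fold change as a ratio of medians.** Robust to the heavy right
  tail of per-gene densities and matches a boxplot-style presentation;
  a mean-ratio alternative is available via `method = "mean"`. The
  background reads that fall inside gene bodies bias the planted-fold
  recovery slightly toward 1 (about −2% at the default signal-to-
  background ratio); this is a property of any in-gene counting
  scheme, not of the estimator.
* **Fixed TR body window.** The +300..+2000 bp window is defined
  relative to the TSS only and deliberately *not* clipped at the TES;
  genes shorter than 1 kb are already excluded by the length filter,
  and clipping would make the two windows' length ratio gene-dependent.
  Genes with zero body-window reads are excluded (with a reported
  count) rather than given infinite ratios.
* **Exact vs asymptotic tests.** The Wilcoxon wrapper uses the exact
  null distribution when $nm \le 64$ and the pooled data are tie-free,
  otherwise the normal approximation with tie correction and 0.5
  continuity correction. The KS wrapper uses exact enumeration when
  $nm \le 10000$ without cross-sample ties, otherwise the asymptotic
  Kolmogorov distribution with effective size $nm/(n+m)$ (ties trigger
  a logged warning). Degenerate inputs (all values identical) return
  p = 1.
* **K-means.** Squared-Euclidean distance on linear (not log) bin
  values, best of 10 restarts under a caller-supplied seed, 50
  iterations max. Cluster labels are re-ordered by descending cluster
  mean signal, so "cluster 1" is always the high-signal cluster and
  assignments are reproducible across runs.
* **Genes shorter than 160 bp** are skipped from metagene profiles
  (sub-bp bins are meaningless) and reported in the `skipped`
  attribute.
* **Neighbor removal** interprets "overlap within a 5-kb window" as
  symmetric: both members of a close pair are removed, since signal
  bleed contaminates both.
* **Fold-change bins** apply the adjusted-p threshold plus the fold
  threshold only (at the 2-fold bin this coincides with the
  $|\log_2 FC| \ge 1$ classification threshold).
* **Annotation releases are inputs.** Gene counts that depend on a
  specific annotation release (e.g. the exact number of qualifying
  intergenic regions on a real genome) are deliberately not reproduced;
  the package treats annotation as data.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate every stage on
synthetic data at sizes chosen for tight statistical bounds at
interactive runtimes: 300-gene genomes (~10 Mb) for fold-recovery runs
(planted folds 2, 4 and 6.5 against a 3× depth confound, recovered
within ±10%), 150 genes for pausing recovery (median TR within ±15% of
the planted promoter:body ratio), 120 genes at doubled depth for peak
localization (argmax within one 10-bp bin of +60/+300), 200 replicate
cohort pairs for KS null calibration, and exhaustive enumeration up to
$n = m = 6$ for the rank statistics.

## Known limitations

* Single-end, fixed-length extension only; no paired-end fragment
  reconstruction.
* bedGraph is the only coverage output format (binary bigWig writing is
  out of scope); tags arrive as BED — converting BAM to tag BED is a
  one-liner with `bedtools bamtobed`.
* The intergenic background model assumes background is uniform enough
  that the median over regions is stable; copy-number-variable genomes
  violate this.
* The traveling ratio is a relative, within-sample statistic; it does
  not identify elongation-rate changes mechanistically, only shifts in
  the promoter/body balance.
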