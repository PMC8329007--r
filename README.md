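# chipmetrics

Quantitative comparison of ChIP-seq signal between conditions when the
mark itself changes globally — with occupancy densities, fixed-bin
metagene profiles, Pol II pausing statistics, and a seeded synthetic-data
generator for end-to-end validation.

## The problem

Comparing a chromatin mark such as H2Bub1 (monoubiquitylated histone
H2B) between wild-type cells and cells lacking a deubiquitylation
module is a trap for standard ChIP-seq normalization: if the mark rises
genome-wide, scaling libraries to equal total reads absorbs exactly the
effect being measured. `chipmetrics` anchors the between-sample scaling
on large intergenic background regions instead. Counts there track
sequencing depth but not genic signal, so median-of-ratios size factors

```
s_j = median_i [ k_ij / (prod_v k_iv)^(1/m) ]
```

over an intergenic region × sample count matrix recover depth
differences untouched by the biology. Per-gene occupancy is then

```
density = (reads in region / region length in bp) / (s_j × 1e-8)
```

and condition-level effects are summarized as the ratio of per-gene
density medians with a Wilcoxon rank-sum comparison. For antibodies
whose total occupancy is expected constant (Pol II, Pol II Ser2P),
total-read factors are used instead, and promoter-proximal pausing is
quantified by the traveling ratio — per-bp signal in the TSS window
(−100..+300 bp) over the early gene body (+300..+2000 bp) — with
two-sample Kolmogorov–Smirnov comparison of cohort distributions.
Fixed-bin metagene profiles (20 × 250 bp flank bins, 160 equal body
bins, 20 × 250 bp flank bins) and TSS-centered profiles (2 kb window,
10 bp bins) localize where on genes the signal changes, and k-means on
the per-gene bin matrix separates signal classes.

Everything is tibble-in / tibble-out and pipe-friendly; interval
arithmetic rides on GenomicRanges/IRanges, plots on ggplot2, and fitted
comparison objects support `tidy()` / `glance()`.

## Worked example

A 300-gene toy genome with a planted 6.5-fold H2Bub1 increase in KO,
deliberately confounded with 3× higher KO sequencing depth:

```r
library(chipmetrics)

genome <- simulate_genome(n_genes = 300, seed = 1)
truth  <- sim_truth(genome$genes, seed = 1, h2bub_fold = 6.5,
                    depth = c(WT = 1, KO = 3))
tags <- list(WT = simulate_tags(truth, "WT", "H2Bub1", genome$chrom_sizes),
             KO = simulate_tags(truth, "KO", "H2Bub1", genome$chrom_sizes))

intergenic <- select_intergenic(genome$genes, genome$chrom_sizes,
                                min_len_bp = 10000, gene_buffer_bp = 5000)
sf <- size_factors_intergenic(region_counts(intergenic, tags))
round(sf, 3)
#>    WT    KO
#> 0.582 1.718
```

The factor ratio (2.95) is the sequencing-depth confound, recovered from
background alone. Densities normalized by these factors expose the
planted biology:

```r
dens <- density_table(genome$genes, tags, sf, chrom_sizes = genome$chrom_sizes)
head(dens, 4)
#> # A tibble: 4 × 4
#>   gene_id   sample raw_count   density
#>   <chr>     <chr>      <dbl>     <dbl>
#> 1 gene_0001 KO          2772 44918475.
#> 2 gene_0001 WT           139  6644596.
#> 3 gene_0002 KO          4306 59226320.
#> 4 gene_0002 WT           226  9170039.

wide <- tidyr::pivot_wider(dens[, c("gene_id", "sample", "density")],
                           names_from = "sample", values_from = "density")
fold_change_summary(wide$WT, wide$KO)
#> [1] 6.459837
rank_sum_test(wide$WT, wide$KO)
#> rank_sum test (normal): W = 0, p = 1.055e-99 (n = 300, m = 300)
```

The median-density fold is 6.46 against the planted 6.5 — the 3× depth
difference lands in the size factors, not in the estimate. Pol II
pausing, planted identically in both conditions, stays put:

```r
pol_wt <- simulate_tags(truth, "WT", "PolII", genome$chrom_sizes)
pol_ko <- simulate_tags(truth, "KO", "PolII", genome$chrom_sizes)
tr_compare(traveling_ratio(genome$genes, pol_wt),
           traveling_ratio(genome$genes, pol_ko))
#> # A tibble: 2 × 3
#>   cohort     n median_tr
#>   <chr>  <int>     <dbl>
#> 1 WT       300      3.76
#> 2 KO       300      3.75
#> ks test (asymptotic): D = 0.16, p = 0.0009239 (n = 300, m = 300)
```

Median traveling ratios are essentially identical (3.76 vs 3.75,
planted promoter:body ratio 4); the small residual D reflects the
depth-dependent estimation noise of per-gene ratios, not a shift in
pausing — `plot_tr_ecdf()` makes that visible as two nearly coincident
cumulative curves.

An entire run (simulation or file inputs → intergenic regions → size
factors → densities → profiles → clustering → traveling ratios → DE
bookkeeping → report) is driven by one config:

```r
cfg <- run_config(outdir = "run1", seed = 1,
                  simulate = list(n_genes = 300, h2bub_fold = 6.5,
                                  depth = c(WT = 1, KO = 3)),
                  intergenic = list(min_len_bp = 10000, gene_buffer_bp = 5000))
res <- run_pipeline(cfg)
```

which writes TSV/BED artifacts plus a `manifest.json` (seed, config
hash) and is byte-identical on rerun.

## Documentation

The methods vignette (`vignettes/chipmetrics-methods.Rmd`) documents
the statistical model, counting conventions, every tunable parameter
with units and rationale, what the synthetic generator does and does
not emulate, and the package's design decisions and limitations.
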