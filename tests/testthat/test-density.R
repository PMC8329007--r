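test_that("tag extension runs in the read direction and clips at zero", {
  plus <- extend_tags(tags_at(100, "+"))
  expect_equal(c(plus$start, plus$end), c(100L, 300L))
  minus <- extend_tags(tags_at(499, "-"))
  expect_equal(c(minus$start, minus$end), c(300L, 500L))
  clipped <- extend_tags(tags_at(50, "-"))
  expect_equal(c(clipped$start, clipped$end), c(0L, 51L))
})

test_that("overlap and coverage counting modes behave as defined", {
  region <- tibble::tibble(chrom = "chr1", start = 250L, end = 400L)
  tag <- tags_at(100)  # extends to [100, 300)
  expect_equal(count_tags(tag, region, mode = "overlap"), 1)
  expect_equal(count_tags(tag, region, mode = "coverage"), 50)
  outside <- tags_at(5000)
  expect_equal(count_tags(outside, region, mode = "overlap"), 0)
  expect_equal(count_tags(outside, region, mode = "coverage"), 0)
})

test_that("a perfect tiling covers the region exactly once", {
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 3000L)
  tiling <- tags_at(seq(1000L, 2800L, by = 200L))  # 10 adjacent fragments
  expect_equal(count_tags(tiling, region, mode = "coverage"),
               region$end - region$start)
})

test_that("the density formula is linear in counts and inverse in the factor", {
  expect_equal(density_value(100, 1000, 1), 1.0e7)
  expect_equal(density_value(100, 1000, 2), 5.0e6)
  expect_equal(density_value(0, 1000, 1), 0)
  expect_error(density_value(1, 1000, 0), "positive")
})

test_that("the density table keeps one shared gene set across samples", {
  genes <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "covered", "chr1", 10000L, 12000L, "+",
    "ko_only", "chr1", 30000L, 32000L, "+",
    "empty",   "chr1", 50000L, 52000L, "+")
  wt <- tags_at(seq(10100L, 11800L, by = 100L))
  ko <- dplyr::bind_rows(wt, tags_at(30500L))
  tab <- density_table(genes, list(WT = wt, KO = ko), c(WT = 1, KO = 1))
  per_sample <- split(tab$gene_id, tab$sample)
  # the zero-read gene is excluded; the KO-only gene appears in both tables
  expect_setequal(per_sample$WT, c("covered", "ko_only"))
  expect_identical(sort(per_sample$WT), sort(per_sample$KO))
  expect_equal(tab$density[tab$gene_id == "ko_only" & tab$sample == "WT"], 0)
  expect_error(density_table(genes, list(WT = wt, KO = ko), c(WT = 1)),
               "KO")
})

test_that("fold-change summary is the ratio of medians", {
  wt <- c(2, 4, 8, 16, 100)
  expect_equal(fold_change_summary(wt, wt * 6.5), 6.5)
  expect_equal(fold_change_summary(wt, wt), 1)
  expect_equal(fold_change_summary(c(1, 2, 3), c(2, 2, 8)), 1)
  expect_equal(fold_change_summary(c(1, 2, 3), c(2, 4, 6), method = "mean"),
               2)
  expect_error(fold_change_summary(c(0, 0, 0), c(1, 2, 3)), "zero")
})

test_that("rank-sum p-values match exhaustive enumeration on small samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)))

  r2 <- rank_sum_test(c(1, 3), c(2, 4))
  expect_equal(r2$p_value, enum_wilcox_p(c(1, 3), c(2, 4)))

  set.seed(17)
  for (rep in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1:60, n + m)
    expect_equal(rank_sum_test(v[1:n], v[-(1:n)])$p_value,
                 enum_wilcox_p(v[1:n], v[-(1:n)]), tolerance = 1e-12)
  }
})

test_that("rank-sum test handles symmetry and degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_gt(rank_sum_test(x, x)$p_value, 0.99)
  deg <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(deg$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("duplicating one sample's tags cancels out of normalized densities", {
  g <- simulate_genome(n_genes = 30, seed = 21)
  truth <- sim_truth(g$genes, seed = 21)
  base <- simulate_tags(truth, "WT", "H2Bub1", g$chrom_sizes)
  dup5 <- dplyr::bind_rows(rep(list(base), 5))
  ig <- select_intergenic(g$genes, g$chrom_sizes, min_len_bp = 10000L,
                          gene_buffer_bp = 5000L)
  sf <- size_factors_intergenic(region_counts(ig, list(A = base, B = dup5)))
  sf <- rescale_factors(sf, "A")
  expect_equal(unname(sf["B"]), 5, tolerance = 1e-12)
  tab <- density_table(g$genes, list(A = base, B = dup5), sf,
                       chrom_sizes = g$chrom_sizes)
  wide <- tidyr::pivot_wider(tab[, c("gene_id", "sample", "density")],
                             names_from = "sample", values_from = "density")
  expect_equal(wide$B, wide$A, tolerance = 1e-9)
})
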