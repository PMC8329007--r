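# A tag grid every `by` bp with 200 bp extension gives exactly flat
# coverage of 200/by once inside the grid, which makes expected bin
# values computable in closed form.
flat_cover_tags <- function(start, end, by = 10L) {
  grid_tags(start - 300L, end + 300L, by = by)
}

test_that("uniform coverage yields a constant 200-bin metagene vector", {
  g <- one_gene(start = 20000L, end = 28000L)
  sizes <- tibble::tibble(chrom = "chr1", size = 60000L)
  tags <- flat_cover_tags(g$start - 5000L, g$end + 5000L)
  mat <- profile_matrix(g, tags, size_factor = 1, chrom_sizes = sizes)
  expect_equal(ncol(mat), 200)
  expect_equal(unname(mat[1, ]), rep(20, 200))
  prof <- average_profile(mat)
  expect_equal(prof$segment,
               rep(c("upstream", "body", "downstream"), c(20, 160, 20)))
})

test_that("binning conserves total signal inside the profiled window", {
  set.seed(23)
  g <- dplyr::bind_rows(
    one_gene(20000L, 26000L, "+", gene_id = "p"),
    one_gene(40000L, 49321L, "-", gene_id = "m"))  # non-multiple length
  sizes <- tibble::tibble(chrom = "chr1", size = 80000L)
  tags <- tibble::tibble(chrom = "chr1",
                         pos5 = as.integer(sample(12000:56000, 3000,
                                                  replace = TRUE)),
                         strand = sample(c("+", "-"), 3000, replace = TRUE))
  sf <- 1.7
  mat <- profile_matrix(g, tags, size_factor = sf, chrom_sizes = sizes)
  w <- attr(mat, "bin_width")
  cov <- tag_coverage(tags, sizes)
  for (i in 1:2) {
    direct <- sum(as.numeric(S4Vectors::window(
      cov[["chr1"]], g$start[i] - 5000L + 1L, g$end[i] + 5000L)))
    expect_equal(sum(mat[i, ] * w[i, ]) * sf, direct, tolerance = 1e-6)
  }
})

test_that("signal near the TSS stays in the first body bins", {
  g <- one_gene(start = 20000L, end = 36000L)  # 100 bp body bins
  sizes <- tibble::tibble(chrom = "chr1", size = 60000L)
  pile <- tags_at(rep(20000L, 50))             # extends [20000, 20200)
  mat <- profile_matrix(g, pile, chrom_sizes = sizes)
  hot <- which(mat[1, ] > 0)
  expect_true(all(hot %in% 21:22))             # first two 100-bp body bins
})

test_that("profiles are invariant under genome reflection", {
  len <- 60000L
  g <- one_gene(start = 20000L, end = 27000L, strand = "+")
  sizes <- tibble::tibble(chrom = "chr1", size = len)
  set.seed(3)
  tags <- tibble::tibble(chrom = "chr1",
                         pos5 = as.integer(sample(14000:33000, 800)),
                         strand = sample(c("+", "-"), 800, replace = TRUE))
  mat <- profile_matrix(g, tags, chrom_sizes = sizes)
  mat_m <- profile_matrix(mirror_genes(g, len), mirror_tags(tags, len),
                          chrom_sizes = sizes)
  expect_equal(unname(mat_m), unname(mat), tolerance = 1e-12)

  tp <- tss_profile(g, tags, chrom_sizes = sizes)
  tp_m <- tss_profile(mirror_genes(g, len), mirror_tags(tags, len),
                      chrom_sizes = sizes)
  expect_equal(tp_m$value, tp$value, tolerance = 1e-12)
})

test_that("averaging is linear and order-invariant", {
  v <- sin(seq_len(200) / 10) + 2
  flipped <- -v + 6  # mean of the two rows is the constant 3
  mat <- rbind(a = v, b = flipped)
  prof <- average_profile(mat)
  expect_equal(prof$value, rep(3, 200))
  expect_equal(average_profile(mat[1, , drop = FALSE])$value, unname(v))
  expect_equal(average_profile(mat[c(2, 1), ])$value, prof$value)
  expect_error(average_profile(mat[0, , drop = FALSE]), "average")
})

test_that("TSS profiles are flat for uniform signal and zero without tags", {
  g <- one_gene(start = 20000L, end = 28000L)
  sizes <- tibble::tibble(chrom = "chr1", size = 60000L)
  flat <- tss_profile(g, flat_cover_tags(18000L, 22000L),
                      chrom_sizes = sizes)
  expect_equal(flat$value, rep(20, 200))
  expect_equal(flat$offset_bp[1], -1000)
  none <- tss_profile(g, tags_at(integer(0)), chrom_sizes = sizes)
  expect_equal(none$value, rep(0, 200))
})

test_that("k-means separates well-separated profile classes perfectly", {
  set.seed(41)
  high_tes <- c(rep(1, 150), seq(1, 9, length.out = 50))
  flat <- rep(1, 200)
  mat <- rbind(
    matrix(rep(high_tes, each = 50), nrow = 50) + rnorm(50 * 200, 0, 0.05),
    matrix(rep(flat, each = 50), nrow = 50) + rnorm(50 * 200, 0, 0.05))
  rownames(mat) <- paste0("g", 1:100)
  cl <- cluster_profiles(mat, k = 2, seed = 4)
  truth <- rep(c(1, 2), each = 50)
  expect_equal(mclust::adjustedRandIndex(cl$assignment$cluster, truth), 1)
  # cluster 1 is canonically the high-signal cluster
  expect_equal(unique(cl$assignment$cluster[1:50]), 1L)
})

test_that("k-means is deterministic and labels duplicates identically", {
  set.seed(8)
  mat <- matrix(rnorm(40 * 20), nrow = 40,
                dimnames = list(paste0("g", 1:40), NULL))
  mat[40, ] <- mat[1, ]  # exact duplicate row
  a <- cluster_profiles(mat, k = 3, seed = 99)
  b <- cluster_profiles(mat, k = 3, seed = 99)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$assignment$cluster[40], a$assignment$cluster[1])
  expect_error(cluster_profiles(mat, k = 41), "exceeds")
  expect_equal(unique(cluster_profiles(mat, k = 1)$assignment$cluster), 1L)
})

test_that("genes shorter than one bin per bp are skipped with a record", {
  g <- dplyr::bind_rows(one_gene(20000L, 28000L, gene_id = "ok"),
                        one_gene(40000L, 40100L, gene_id = "short"))
  sizes <- tibble::tibble(chrom = "chr1", size = 60000L)
  expect_message(
    mat <- profile_matrix(g, tags_at(20500L), chrom_sizes = sizes),
    "skipped")
  expect_equal(rownames(mat), "ok")
  expect_equal(attr(mat, "skipped"), "short")
})
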