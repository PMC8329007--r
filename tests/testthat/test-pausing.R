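test_that("uniform read placement gives a traveling ratio of exactly 1", {
  g <- one_gene(start = 20000L, end = 30000L)
  # one 5' position every 10 bp across the whole windowed span
  tags <- grid_tags(19000L, 29990L)
  tr <- traveling_ratio(g, tags)
  expect_equal(tr$tr, 1)
  expect_equal(tr$tss_count, 40)
  expect_equal(tr$body_count, 170)
})

test_that("a constructed promoter:body ratio is returned exactly", {
  g <- one_gene(start = 20000L, end = 30000L)
  # 5 reads per 10 bp in the TSS window, 1 per 10 bp in the body
  tss_reads <- tags_at(rep(seq(19900L, 20290L, by = 10L), each = 5))
  body_reads <- grid_tags(20300L, 21990L)
  tr <- traveling_ratio(g, dplyr::bind_rows(tss_reads, body_reads))
  expect_equal(tr$tr, 5)
})

test_that("the count basis and density basis differ as documented", {
  g <- one_gene(start = 20000L, end = 30000L)
  tags <- dplyr::bind_rows(
    tags_at(seq(19900L, 20290L, by = 10L)),            # 40 in 400 bp
    tags_at(seq(20300L, 21900L, by = 100L))            # 17 in 1700 bp
  )
  dens <- traveling_ratio(g, tags, cfg = pausing_config(basis = "density"))
  cnt <- traveling_ratio(g, tags, cfg = pausing_config(basis = "count"))
  expect_equal(dens$tr, 10)
  expect_equal(cnt$tr, 40 / 17, tolerance = 1e-12)
})

test_that("the traveling ratio ignores global depth scaling", {
  g <- simulate_genome(n_genes = 20, seed = 33)
  truth <- sim_truth(g$genes, seed = 33)
  tags <- simulate_tags(truth, "WT", "PolII", g$chrom_sizes)
  tr1 <- traveling_ratio(g$genes, tags, size_factor = 1)
  tr3 <- traveling_ratio(g$genes, dplyr::bind_rows(tags, tags, tags),
                         size_factor = 3)
  shared <- intersect(tr1$gene_id, tr3$gene_id)
  expect_equal(tr3$tr[match(shared, tr3$gene_id)],
               tr1$tr[match(shared, tr1$gene_id)], tolerance = 1e-12)
})

test_that("genes without body reads are excluded, not infinite", {
  g <- dplyr::bind_rows(one_gene(20000L, 30000L, gene_id = "ok"),
                        one_gene(50000L, 60000L, gene_id = "nobody"))
  tags <- dplyr::bind_rows(grid_tags(19000L, 29990L),
                           tags_at(rep(50000L, 8)))  # TSS reads only
  expect_message(tr <- traveling_ratio(g, tags), "excluded")
  expect_equal(tr$gene_id, "ok")
  expect_equal(attr(tr, "n_excluded"), 1)
})

test_that("KS statistic and p match exhaustive enumeration on small samples", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$D, 1)
  expect_equal(r$p_value, 0.1)
  o <- enum_ks(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$D, o$D)
  expect_equal(r$p_value, o$p)

  set.seed(19)
  for (rep in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- runif(n + m)
    got <- ks_two_sample(v[1:n], v[-(1:n)])
    want <- enum_ks(v[1:n], v[-(1:n)])
    expect_equal(got$D, want$D, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("identical samples give D = 0 and p = 1", {
  x <- c(1.5, 2.5, 9)
  r <- suppressWarnings(ks_two_sample(x, x))
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
})

test_that("KS is invariant under common strictly monotone transforms", {
  set.seed(29)
  x <- rlnorm(40); y <- rlnorm(45, meanlog = 0.4)
  a <- ks_two_sample(x, y)
  b <- ks_two_sample(log(x), log(y))
  expect_equal(b$D, a$D)
  expect_equal(b$p_value, a$p_value)
})

test_that("asymptotic KS p agrees with a permutation estimate", {
  set.seed(37)
  x <- rnorm(120); y <- rnorm(110, mean = 0.45)
  got <- ks_two_sample(x, y)   # n*m > 10000 -> asymptotic
  expect_equal(got$method, "asymptotic")
  d_of <- function(a, b) {
    grid <- sort(c(a, b))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  pooled <- c(x, y)
  perm <- replicate(4000, {
    idx <- sample(230, 120)
    d_of(pooled[idx], pooled[-idx])
  })
  p_perm <- mean(perm >= got$D - 1e-12)
  expect_lt(got$p_value, 0.05)
  expect_lt(abs(log(got$p_value / max(p_perm, 1 / 4000))), log(2.5))
})

test_that("cohort comparison reports ECDFs, medians and the KS result", {
  set.seed(43)
  tr_a <- tibble::tibble(gene_id = paste0("a", 1:50), tr = rlnorm(50, 1))
  tr_b <- tibble::tibble(gene_id = paste0("b", 1:60), tr = rlnorm(60, 1.5))
  cmp <- tr_compare(tr_a, tr_b)
  expect_s3_class(cmp, "tr_comparison")
  expect_equal(cmp$summary$n, c(50, 60))
  expect_equal(glance(cmp)$D, cmp$ks$D)
  e <- tr_ecdf(tr_a)
  expect_equal(e$ecdf[nrow(e)], 1)
  expect_true(!is.unsorted(e$tr))
})
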