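test_that("expression filter applies the strict reads-per-kb rule", {
  genes <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand, ~median_tx_len_kb,
    "a", "chr1", 0L, 2000L, "+", 2,
    "b", "chr1", 10000L, 11000L, "+", 1,
    "c", "chr1", 20000L, 220000L, "+", 200)
  recs <- tibble::tibble(gene_id = c("a", "b", "c"),
                         base_median = c(25, 10, 1000),
                         log2fc = 0, padj = 1)
  kept <- filter_expressed(recs, genes)
  expect_equal(kept$gene_id, "a")      # 12.5 > 10; 10 is not > 10; 5 is not
  expect_error(
    filter_expressed(tibble::tibble(gene_id = "zz", base_median = 1,
                                    log2fc = 0, padj = 1), genes),
    "zz")
})

test_that("raising the expression threshold never adds genes", {
  set.seed(2)
  genes <- tibble::tibble(gene_id = paste0("g", 1:50), chrom = "chr1",
                          start = seq(0L, by = 10000L, length.out = 50),
                          end = seq(5000L, by = 10000L, length.out = 50),
                          strand = "+",
                          median_tx_len_kb = runif(50, 0.5, 10))
  recs <- tibble::tibble(gene_id = genes$gene_id,
                         base_median = rlnorm(50, 3, 1.5),
                         log2fc = 0, padj = 1)
  prev <- NULL
  for (thr in c(1, 5, 10, 50, 200)) {
    ids <- filter_expressed(recs, genes, min_density = thr)$gene_id
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("neighbor removal is symmetric within the flanking window", {
  far <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "a", "chr1", 0L, 1000L, "+",
    "b", "chr1", 21000L, 22000L, "-")
  expect_equal(remove_neighbors(far)$gene_id, c("a", "b"))  # 20 kb apart

  near <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "a", "chr1", 0L, 1000L, "+",
    "b", "chr1", 4000L, 5000L, "-")
  expect_equal(nrow(remove_neighbors(near)), 0)             # 3 kb: both go

  single <- one_gene()
  expect_equal(remove_neighbors(single)$gene_id, "g1")
})

test_that("intergenic selection matches direct complement arithmetic", {
  genes <- one_gene(start = 400000L, end = 500000L)
  sizes <- tibble::tibble(chrom = "chr1", size = 1000000L)
  ig <- select_intergenic(genes, sizes)
  expect_equal(ig$start, c(0L, 510000L))
  expect_equal(ig$end, c(390000L, 1000000L))

  # a gene-free chromosome shorter than the length floor yields nothing
  tiny <- tibble::tibble(chrom = "chrS", size = 50000L)
  expect_equal(nrow(select_intergenic(genes[0, ], tiny)), 0)
})

test_that("intergenic selection agrees with a per-bp oracle on random genomes", {
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    starts <- sort(sample(seq(0L, 180000L, by = 100L), n))
    genes <- tibble::tibble(gene_id = paste0("g", 1:n), chrom = "chr1",
                            start = starts,
                            end = starts + sample(500:15000, n),
                            strand = "+", median_tx_len_kb = 1)
    sizes <- tibble::tibble(chrom = "chr1", size = 250000L)
    got <- select_intergenic(genes, sizes, min_len_bp = 5000L,
                             gene_buffer_bp = 2000L)
    want <- bp_intergenic(genes, 250000L, 2000L, 5000L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # never intersects a buffered gene span
    for (i in seq_len(nrow(genes))) {
      expect_true(all(got$end <= genes$start[i] - 2000L |
                        got$start >= genes$end[i] + 2000L))
    }
  }
})

test_that("TSS and body windows are strand-aware with fixed lengths", {
  plus <- one_gene(start = 1000L, end = 5000L, strand = "+")
  minus <- one_gene(start = 1000L, end = 5000L, strand = "-")
  tp <- tss_window(plus, 100, 300)
  tm <- tss_window(minus, 100, 300)
  expect_equal(c(tp$start, tp$end), c(900L, 1300L))
  expect_equal(c(tm$start, tm$end), c(4700L, 5100L))
  expect_equal(tp$end - tp$start, tm$end - tm$start)

  bp <- suppressMessages(body_window(plus, 300, 2000))
  bm <- suppressMessages(body_window(minus, 300, 2000))
  expect_equal(c(bp$start, bp$end), c(1300L, 3000L))
  expect_equal(c(bm$start, bm$end), c(3000L, 4700L))

  expect_error(tss_window(plus, 0, 0), "degenerate")
})

test_that("windows clip at coordinate bounds and flag the clipping", {
  g <- one_gene(start = 50L, end = 5000L, strand = "+")
  w <- tss_window(g, 100, 300)
  expect_equal(w$start, 0L)
  expect_true(w$clipped)
  # short gene: body window deliberately passes the TES, with a message
  short <- one_gene(start = 1000L, end = 2500L, strand = "+")
  expect_message(bw <- body_window(short, 300, 2000), "TES")
  expect_equal(bw$end, 3000L)
})

test_that("window construction is invariant under genome reflection", {
  len <- 100000L
  genes <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand,
    "a", "chr1", 10000L, 18000L, "+",
    "b", "chr1", 40000L, 42000L, "-")
  mirrored <- mirror_genes(genes, len)
  for (fun in list(function(g) tss_window(g, 100, 300),
                   function(g) suppressMessages(body_window(g, 300, 2000)))) {
    w <- fun(genes)
    wm <- fun(mirrored)
    # reflected window of the reflected gene equals the original window
    expect_equal(len - wm$end, w$start)
    expect_equal(len - wm$start, w$end)
  }
})

test_that("traveling-ratio gene filter applies both strict thresholds", {
  genes <- make_genes(
    ~gene_id, ~chrom, ~start, ~end, ~strand, ~median_tx_len_kb,
    "a", "chr1", 0L, 3000L, "+", 2,
    "b", "chr1", 10000L, 13000L, "+", 2,
    "c", "chr1", 20000L, 20900L, "+", 2)
  recs <- tibble::tibble(gene_id = c("a", "b", "c"),
                         base_median = c(500, 150, 500),
                         log2fc = 0, padj = 1)
  expect_equal(tr_gene_set(genes, recs)$gene_id, "a")
})
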