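# Metagene and TSS-centered average profiles.  Gene bodies are divided
# into a fixed number of equal bins (default 160) regardless of length;
# 5 kb flanks are added on both sides in 20 fixed 250-bp bins, giving a
# 200-bin vector oriented 5' -> 3'.  Bin values are mean per-bp coverage
# over the (possibly fractional-width) bin, divided by the size factor,
# so bins of unequal width are directly comparable and total signal is
# conserved.

#' Profile configuration
#'
#' @param n_body_bins Equal bins across the gene body (default 160).
#' @param flank_bp Flank added on each side in bp (default 5000).
#' @param n_flank_bins Bins per flank (default 20, i.e. 250 bp/bin).
#' @param tss_window_bp Total width of the TSS-centered window (default
#'   2000 bp).
#' @param tss_bin_bp Bin width for the TSS profile (default 10 bp).
#' @param extension_bp Tag extension for coverage (default 200 bp).
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(n_body_bins = 160L, flank_bp = 5000L,
                           n_flank_bins = 20L, tss_window_bp = 2000L,
                           tss_bin_bp = 10L, extension_bp = 200L) {
  if (n_body_bins < 1) abort("n_body_bins must be >= 1")
  if (flank_bp %% n_flank_bins != 0) {
    abort("flank_bp must be a multiple of n_flank_bins")
  }
  if (tss_window_bp %% (2L * tss_bin_bp) != 0) {
    abort("tss_window_bp must be an even multiple of tss_bin_bp")
  }
  structure(list(n_body_bins = n_body_bins, flank_bp = flank_bp,
                 n_flank_bins = n_flank_bins, tss_window_bp = tss_window_bp,
                 tss_bin_bp = tss_bin_bp, extension_bp = extension_bp),
            class = "profile_config")
}

# per-bp coverage over [start0, end0) on one chromosome, zero-padded
# outside the chromosome
window_coverage <- function(cov_chrom, start0, end0) {
  n <- end0 - start0
  out <- numeric(n)
  lo <- max(start0, 0L)
  hi <- min(end0, length(cov_chrom))
  if (hi > lo) {
    out[(lo - start0 + 1L):(hi - start0)] <-
      as.numeric(S4Vectors::window(cov_chrom, lo + 1L, hi))
  }
  out
}

# Sum per-bp values over bins with real-valued edges (in window offsets),
# treating coverage as piecewise-constant per bp.  Exact: the sums over
# all bins add to sum(v) when the edges span the window.
fractional_bin_sums <- function(v, edges) {
  cum <- c(0, cumsum(v))
  interp <- function(p) {
    i <- pmin(floor(p), length(v))
    f <- p - i
    cum[i + 1] + ifelse(f > 0, f * v[pmin(i + 1, length(v))], 0)
  }
  diff(interp(edges))
}

profile_bin_edges <- function(gene_len, cfg) {
  fb <- cfg$flank_bp / cfg$n_flank_bins
  c(seq(0, cfg$flank_bp, by = fb)[-(cfg$n_flank_bins + 1L)],
    cfg$flank_bp + (0:cfg$n_body_bins) * gene_len / cfg$n_body_bins,
    cfg$flank_bp + gene_len + seq(fb, cfg$flank_bp, by = fb))
}

#' Per-gene metagene signal matrix
#'
#' For each gene the window TSS - `flank_bp` .. TES + `flank_bp` is
#' extracted from the extended-tag coverage, the body is split into
#' `n_body_bins` equal bins and each flank into `n_flank_bins` fixed
#' bins; every bin value is its mean per-bp coverage divided by the size
#' factor.  Minus-strand genes are reversed so index 1 is always 5'-most.
#' Genes shorter than `n_body_bins` bp are skipped (sub-bp bins are
#' meaningless); their ids are returned in the `skipped` attribute.
#'
#' @param genes Gene tibble.
#' @param tags Tag tibble for one sample.
#' @param size_factor Positive scalar size factor for the sample.
#' @param cfg A [profile_config()].
#' @param chrom_sizes Chromosome sizes tibble.
#' @return Numeric matrix, genes x (2 * n_flank_bins + n_body_bins), with
#'   gene ids as rownames and attributes `skipped` and `bin_width`.
#' @export
profile_matrix <- function(genes, tags, size_factor = 1,
                           cfg = profile_config(), chrom_sizes = NULL) {
  if (size_factor <= 0) abort("size_factor must be positive")
  nbin <- 2L * cfg$n_flank_bins + cfg$n_body_bins
  lens <- genes$end - genes$start
  skip <- lens < cfg$n_body_bins
  if (any(skip)) {
    inform(paste0(sum(skip), " gene(s) shorter than ", cfg$n_body_bins,
                  " bp skipped from the metagene profile"))
  }
  keep <- genes[!skip, , drop = FALSE]
  cov <- tag_coverage(tags, chrom_sizes %||% infer_chrom_sizes(genes, tags),
                      extension_bp = cfg$extension_bp)
  mat <- matrix(0, nrow = nrow(keep), ncol = nbin,
                dimnames = list(keep$gene_id, NULL))
  widths <- matrix(0, nrow = nrow(keep), ncol = nbin)
  for (i in seq_len(nrow(keep))) {
    g <- keep[i, ]
    glen <- g$end - g$start
    v <- window_coverage(cov[[g$chrom]], g$start - cfg$flank_bp,
                         g$end + cfg$flank_bp)
    edges <- profile_bin_edges(glen, cfg)
    w <- diff(edges)
    vals <- fractional_bin_sums(v, edges) / w / size_factor
    if (g$strand == "-") {
      vals <- rev(vals)
      w <- rev(w)
    }
    mat[i, ] <- vals
    widths[i, ] <- w
  }
  attr(mat, "skipped") <- genes$gene_id[skip]
  attr(mat, "bin_width") <- widths
  attr(mat, "size_factor") <- size_factor
  mat
}

# fallback chromosome sizes when none are given: far end of any feature
infer_chrom_sizes <- function(genes, tags) {
  feats <- bind_rows(tibble(chrom = genes$chrom, pos = genes$end),
                     tibble(chrom = tags$chrom, pos = tags$pos5 + 1L))
  feats |>
    group_by(.data$chrom) |>
    summarise(size = max(.data$pos) + 10000L, .groups = "drop")
}

#' Average metagene profile over genes
#'
#' Unweighted arithmetic mean per bin over the rows of a
#' [profile_matrix()].
#'
#' @param mat Per-gene profile matrix (genes x bins).
#' @param cfg The [profile_config()] used to build it (for bin labels).
#' @param sample Optional sample label attached to the output.
#' @return Tibble (`sample`, `bin`, `segment`, `value`): `segment` is
#'   `upstream`, `body` or `downstream`; `bin` is 1-based 5' -> 3'.
#' @export
average_profile <- function(mat, cfg = profile_config(), sample = NA_character_) {
  if (is.null(dim(mat)) || nrow(mat) == 0) {
    abort("no gene profiles to average")
  }
  nf <- cfg$n_flank_bins; nb <- cfg$n_body_bins
  tibble(sample = sample,
         bin = seq_len(ncol(mat)),
         segment = rep(c("upstream", "body", "downstream"),
                       times = c(nf, nb, nf)),
         value = colMeans(mat))
}

#' Metagene profile in one call
#'
#' Convenience wrapper: [profile_matrix()] then [average_profile()].
#' @inheritParams profile_matrix
#' @param sample Optional sample label.
#' @return Tibble as in [average_profile()].
#' @export
metagene_profile <- function(genes, tags, size_factor = 1,
                             cfg = profile_config(), chrom_sizes = NULL,
                             sample = NA_character_) {
  mat <- profile_matrix(genes, tags, size_factor, cfg, chrom_sizes)
  average_profile(mat, cfg, sample = sample)
}

#' TSS-centered average profile
#'
#' Extracts extended-tag coverage in a `tss_window_bp` window centered on
#' each TSS (strand-oriented), bins it at `tss_bin_bp`, normalizes by the
#' size factor, and averages over genes.
#'
#' @inheritParams profile_matrix
#' @param sample Optional sample label.
#' @return Tibble (`sample`, `bin`, `offset_bp`, `value`); `offset_bp` is
#'   the bin start relative to the TSS (bin 1 starts at
#'   `-tss_window_bp / 2`).
#' @export
tss_profile <- function(genes, tags, size_factor = 1, cfg = profile_config(),
                        chrom_sizes = NULL, sample = NA_character_) {
  if (size_factor <= 0) abort("size_factor must be positive")
  half <- cfg$tss_window_bp %/% 2L
  nbin <- cfg$tss_window_bp %/% cfg$tss_bin_bp
  cov <- tag_coverage(tags, chrom_sizes %||% infer_chrom_sizes(genes, tags),
                      extension_bp = cfg$extension_bp)
  win <- strand_window(genes, -half, half)
  acc <- matrix(0, nrow = nrow(genes), ncol = nbin)
  for (i in seq_len(nrow(genes))) {
    v <- window_coverage(cov[[win$chrom[i]]], win$start[i], win$end[i])
    if (win$strand[i] == "-") v <- rev(v)
    acc[i, ] <- colMeans(matrix(v, nrow = cfg$tss_bin_bp)) / size_factor
  }
  tibble(sample = sample, bin = seq_len(nbin),
         offset_bp = -half + (seq_len(nbin) - 1L) * cfg$tss_bin_bp,
         value = colMeans(acc))
}

#' k-means clustering of per-gene signal profiles
#'
#' Clusters the rows of a per-gene bin matrix with k-means
#' (squared-Euclidean distance on linear bin values), taking the best of
#' `n_restarts` random starts.  Cluster labels are re-ordered by
#' descending cluster mean signal so that cluster 1 is always the
#' high-signal cluster and labels are reproducible.
#'
#' @param mat Numeric matrix, genes x bins, gene ids as rownames.
#' @param k Number of clusters (`1 <= k <= nrow(mat)`).
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Random restarts (default 10).
#' @return An object of class `profile_clusters`: list with `assignment`
#'   (tibble `gene_id`, `cluster`), `k`, `seed`, `tot_withinss`,
#'   `centers`.
#' @export
cluster_profiles <- function(mat, k, seed = 1L, n_restarts = 10L) {
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(mat)) abort("k exceeds the number of genes")
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fit <- suppressWarnings(
    kmeans(mat, centers = k, nstart = n_restarts, iter.max = 50))
  ord <- order(rowMeans(fit$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(list(
    assignment = tibble(gene_id = rownames(mat),
                        cluster = relabel[fit$cluster]),
    k = k, seed = seed, tot_withinss = fit$tot.withinss,
    centers = fit$centers[ord, , drop = FALSE]),
    class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("k-means profile clustering: k =", x$k, ", seed =", x$seed,
      ", within-SS =", signif(x$tot_withinss, 6), "\n")
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.profile_clusters <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.profile_clusters <- function(x, ...) {
  tibble(k = x$k, seed = x$seed, tot_withinss = x$tot_withinss,
         n_genes = nrow(x$assignment))
}
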