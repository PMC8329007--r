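# Seeded generator of toy genomes, WT/KO ChIP-seq tag libraries, and DE
# tables with the statistical structure the analysis assumes: a
# promoter-proximal Pol II peak near TSS +60 bp, an H2Bub1 gene-body
# signal with its maximum near TSS +300 bp over a body-wide plateau, a
# Ser2P signal rising toward the TES, uniform intergenic background, a
# per-sample depth factor, and per-gene KO/WT enrichment folds.  All
# randomness flows from one explicit seed.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Simulate a toy genome annotation
#'
#' Places `n_genes` non-overlapping genes on one chromosome, separated by
#' random gaps, with random strands.  Deterministic for a given seed.
#'
#' @param n_genes Number of genes.
#' @param gene_len_range Length-2 vector: min/max gene length in bp.
#' @param gap_range Length-2 vector: min/max intergenic gap in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return List with `genes` (gene tibble) and `chrom_sizes`.
#' @export
simulate_genome <- function(n_genes = 300L, gene_len_range = c(2000L, 8000L),
                            gap_range = c(20000L, 40000L), seed = 1L,
                            chrom = "sim1") {
  if (any(c(gene_len_range, gap_range) <= 0)) {
    abort("infeasible packing: gene_len_range and gap_range must be positive")
  }
  with_local_seed(seed, {
    if (n_genes == 0) {
      size <- round(runif(1, gap_range[1], gap_range[2]))
      return(list(genes = empty_genes(),
                  chrom_sizes = tibble(chrom = chrom, size = as.integer(size))))
    }
    lens <- round(runif(n_genes, gene_len_range[1], gene_len_range[2]))
    gaps <- round(runif(n_genes + 1L, gap_range[1], gap_range[2]))
    starts <- cumsum(gaps[seq_len(n_genes)] + c(0, lens[-n_genes]))
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      median_tx_len_kb = lens / 1000)
    size <- genes$end[n_genes] + gaps[n_genes + 1L]
    list(genes = genes,
         chrom_sizes = tibble(chrom = chrom, size = as.integer(size)))
  })
}

#' Ground truth for a tag simulation
#'
#' Draws per-gene signal parameters and fixes the global shape constants.
#' Rates are per-bp expected fragment counts at depth 1.
#'
#' @param genes Gene tibble (e.g. from [simulate_genome()]).
#' @param seed Integer seed; recorded in the output and used to derive
#'   the per-library seeds of [simulate_tags()].
#' @param background_rate Intergenic background, fragments per bp
#'   (default 0.001).
#' @param body_rate Median gene-body fragment rate per bp (default 0.05).
#' @param body_rate_sdlog Log-normal spread of per-gene body rates
#'   (default 0.3).
#' @param h2bub_fold KO/WT H2Bub1 enrichment fold, scalar or per-gene
#'   (default 1).
#' @param pausing_ratio Planted promoter:body per-bp signal ratio over
#'   the -100..+300 TSS window, scalar or per-gene (default 4; must be
#'   >= 0.75 so the promoter-peak intensity is non-negative).
#' @param depth Named per-sample depth factors (default `c(WT = 1, KO = 1)`).
#' @param peak_center_bp,peak_sd_bp Pol II promoter peak: Gaussian center
#'   (+60) and sd (50).
#' @param h2bub_mode_bp,h2bub_peak_sd_bp,h2bub_peak_height H2Bub1 body
#'   shape: a plateau of height 1 with a Gaussian bump of the given
#'   height (default 0.8) centered at +300.
#' @param tes_cluster_frac Fraction of genes with a strong Ser2P TES
#'   accumulation (cluster-1-like; default 0.5).
#' @param frag_len_bp Implied fragment length; tag 5' ends are placed so
#'   a `frag_len_bp` extension reconstructs the fragment (default 200).
#' @param read_len_bp Read length written to BED output (default 50).
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(genes, seed = 1L, background_rate = 0.001,
                      body_rate = 0.05, body_rate_sdlog = 0.3,
                      h2bub_fold = 1, pausing_ratio = 4,
                      depth = c(WT = 1, KO = 1),
                      peak_center_bp = 60, peak_sd_bp = 50,
                      h2bub_mode_bp = 300, h2bub_peak_sd_bp = 100,
                      h2bub_peak_height = 0.8,
                      tes_cluster_frac = 0.5,
                      frag_len_bp = 200L, read_len_bp = 50L) {
  if (any(pausing_ratio < 0.75)) {
    abort("pausing_ratio must be >= 0.75 (promoter peak intensity would be negative)")
  }
  if (any(depth <= 0)) abort("depth factors must be positive")
  n <- nrow(genes)
  params <- with_local_seed(seed, tibble(
    gene_id = genes$gene_id,
    body_rate = body_rate * exp(rnorm(n, 0, body_rate_sdlog) -
                                  body_rate_sdlog^2 / 2),
    h2bub_fold = rep_len(h2bub_fold, n),
    pausing_ratio = rep_len(pausing_ratio, n),
    tes_class = ifelse(runif(n) < tes_cluster_frac, 1L, 2L)))
  structure(list(genes = genes, gene_params = params, seed = as.integer(seed),
                 background_rate = background_rate, depth = depth,
                 peak_center_bp = peak_center_bp, peak_sd_bp = peak_sd_bp,
                 h2bub_mode_bp = h2bub_mode_bp,
                 h2bub_peak_sd_bp = h2bub_peak_sd_bp,
                 h2bub_peak_height = h2bub_peak_height,
                 frag_len_bp = as.integer(frag_len_bp),
                 read_len_bp = as.integer(read_len_bp)),
            class = "sim_truth")
}

# fragment centers (relative to TSS, in transcription orientation) for
# one gene and mark, at the given effective rate scale
sim_gene_positions <- function(L, rate, mark, truth) {
  u <- numeric(0)
  if (mark == "PolII") {
    n_body <- rpois(1, rate * L)
    u <- c(u, runif(n_body, 0, L))
    # extra promoter-peak intensity so that the expected per-bp signal in
    # the -100..+300 window is pausing_ratio x the body per-bp rate
    # (uniform body already contributes over the +0..+300 part)
    a <- rate * (400 * attr(rate, "pausing_ratio") - 300)
    n_peak <- rpois(1, max(0, a))
    u <- c(u, rnorm(n_peak, truth$peak_center_bp, truth$peak_sd_bp))
  } else if (mark == "H2Bub1") {
    # plateau with a smooth 0 -> 1 onset over the first 100 bp ...
    n_plat <- rpois(1, rate * L)
    up <- runif(n_plat, 0, L)
    up <- up[runif(n_plat) < pmin(up / 100, 1)]
    # ... plus a Gaussian bump peaking at +300
    bump_mass <- rate * truth$h2bub_peak_height *
      sqrt(2 * pi) * truth$h2bub_peak_sd_bp
    n_bump <- rpois(1, bump_mass)
    ub <- rnorm(n_bump, truth$h2bub_mode_bp, truth$h2bub_peak_sd_bp)
    u <- c(up, ub[ub >= 0 & ub < L])
  } else { # PolII_Ser2P: signal rising toward the TES
    n_base <- rpois(1, rate * L * 0.5)
    n_ramp <- rpois(1, rate * L * 0.5)
    u <- c(runif(n_base, 0, L), L * sqrt(runif(n_ramp)))
    if (attr(rate, "tes_class") == 1L) {
      n_tes <- rpois(1, rate * 900)
      ut <- rnorm(n_tes, L, 300)
      u <- c(u, ut[ut >= 0 & ut < L + 3000])
    }
  }
  u
}

#' Simulate a ChIP-seq tag library
#'
#' Draws Poisson fragment counts whose intensity is
#' `depth x (gene term + background)`, places fragment centers according
#' to the mark's shape, and emits stranded 5' tag positions such that
#' extension to `frag_len_bp` reconstructs the fragments.  In `KO`
#' samples the H2Bub1 gene term is multiplied by the per-gene
#' `h2bub_fold`.  Deterministic for a given truth seed, sample and mark.
#'
#' @param truth A [sim_truth()].
#' @param sample `"WT"` or `"KO"` (must be named in `truth$depth`).
#' @param mark `"PolII"`, `"PolII_Ser2P"` or `"H2Bub1"`.
#' @param chrom_sizes Chromosome sizes tibble.
#' @return Tag tibble sorted by position.
#' @export
simulate_tags <- function(truth, sample, mark = c("PolII", "PolII_Ser2P",
                                                  "H2Bub1"),
                          chrom_sizes) {
  mark <- match.arg(mark)
  if (!sample %in% names(truth$depth)) {
    abort(paste0("sample '", sample, "' has no depth factor in the truth"))
  }
  d <- truth$depth[[sample]]
  subseed <- (truth$seed + 101 * match(sample, names(truth$depth)) +
                977 * match(mark, c("PolII", "PolII_Ser2P", "H2Bub1"))) %%
    2147483647
  genes <- truth$genes
  params <- truth$gene_params
  with_local_seed(subseed, {
    # background over every chromosome
    n_bg <- rpois(nrow(chrom_sizes), truth$background_rate * d *
                    chrom_sizes$size)
    bg <- tibble(
      chrom = rep(chrom_sizes$chrom, n_bg),
      pos = unlist(purrr::map2(chrom_sizes$size, n_bg,
                               function(s, n) runif(n, 0, s))))
    # gene terms
    gene_pos <- purrr::map(seq_len(nrow(genes)), function(i) {
      L <- genes$end[i] - genes$start[i]
      rate <- params$body_rate[i] * d
      if (mark == "H2Bub1" && sample == "KO") {
        rate <- rate * params$h2bub_fold[i]
      }
      attr(rate, "pausing_ratio") <- params$pausing_ratio[i]
      attr(rate, "tes_class") <- params$tes_class[i]
      u <- sim_gene_positions(L, rate, mark, truth)
      pos <- if (genes$strand[i] == "+") genes$start[i] + u
      else (genes$end[i] - 1) - u
      tibble(chrom = genes$chrom[i], pos = pos)
    })
    centers <- bind_rows(bg, bind_rows(gene_pos))
    sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
    keep <- centers$pos >= 0 & centers$pos < unname(sz[centers$chrom])
    centers <- centers[keep, , drop = FALSE]
    # fragment center -> stranded 5' tag position
    half <- truth$frag_len_bp %/% 2L
    strand <- ifelse(runif(nrow(centers)) < 0.5, "+", "-")
    pos5 <- ifelse(strand == "+", round(centers$pos) - half,
                   round(centers$pos) + half - 1L)
    pos5 <- pmax(0L, pmin(as.integer(pos5), unname(sz[centers$chrom]) - 1L))
    tibble(chrom = centers$chrom, pos5 = as.integer(pos5),
           strand = strand) |>
      arrange(.data$chrom, .data$pos5, .data$strand)
  })
}

#' Simulate a differential-expression result table
#'
#' Null genes get centered log2 fold-change noise and uniform p-values;
#' planted up/down genes get a shifted log2fc and near-zero p-values.
#' Benjamini-Hochberg adjustment is applied.
#'
#' @param n_genes Number of genes.
#' @param frac_up,frac_down Fractions of planted up-/down-regulated genes
#'   (sum must be <= 1).
#' @param effect_log2fc Planted |log2 fold change| (default 3).
#' @param seed Integer seed.
#' @param null_sd SD of the null log2fc noise (default 0.25).
#' @param effect_sd SD around the planted effect (default 0.25).
#' @return Tibble (`gene_id`, `base_median`, `log2fc`, `pvalue`, `padj`,
#'   `truth`), `truth` in `{null, up, down}`.
#' @export
simulate_de_table <- function(n_genes = 1000L, frac_up = 0.05,
                              frac_down = 0.05, effect_log2fc = 3,
                              seed = 1L, null_sd = 0.25, effect_sd = 0.25) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    abort("frac_up and frac_down must be non-negative and sum to <= 1")
  }
  with_local_seed(seed, {
    n_up <- round(n_genes * frac_up)
    n_down <- round(n_genes * frac_down)
    truth <- sample(rep(c("up", "down", "null"),
                        c(n_up, n_down, n_genes - n_up - n_down)))
    log2fc <- rnorm(n_genes, 0, null_sd)
    log2fc[truth == "up"] <- rnorm(n_up, effect_log2fc, effect_sd)
    log2fc[truth == "down"] <- rnorm(n_down, -effect_log2fc, effect_sd)
    pvalue <- runif(n_genes)
    pvalue[truth != "null"] <- runif(n_up + n_down) * 1e-8
    tibble(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
           base_median = exp(rnorm(n_genes, log(200), 1)),
           log2fc = log2fc, pvalue = pvalue,
           padj = adjust_bh(pvalue), truth = truth)
  })
}
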