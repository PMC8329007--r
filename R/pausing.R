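# Pol II traveling ratio (pausing index): the ratio of normalized Pol II
# signal in the promoter-proximal TSS window (-100..+300 bp) to that in
# the fixed gene-body window (+300..+2000 bp).  The same size factor
# scales both windows and cancels, so the statistic is depth-free; cohort
# distributions are compared by their ECDFs with the two-sample KS test.

#' Pausing (traveling-ratio) configuration
#'
#' @param tss_up_bp,tss_down_bp TSS window extent (default -100..+300).
#' @param body_from_bp,body_to_bp Body window in bp downstream of the TSS
#'   (default +300..+2000).
#' @param basis `"density"` (per-bp rates; default, since the two windows
#'   have unequal lengths) or `"count"` (raw read ratio).
#' @return A list of class `pausing_config`.
#' @export
pausing_config <- function(tss_up_bp = 100L, tss_down_bp = 300L,
                           body_from_bp = 300L, body_to_bp = 2000L,
                           basis = c("density", "count")) {
  if (body_to_bp <= body_from_bp) abort("body_to_bp must exceed body_from_bp")
  structure(list(tss_up_bp = tss_up_bp, tss_down_bp = tss_down_bp,
                 body_from_bp = body_from_bp, body_to_bp = body_to_bp,
                 basis = match.arg(basis)),
            class = "pausing_config")
}

#' Per-gene traveling ratio
#'
#' Reads are assigned to the strand-aware TSS and body windows by their
#' 5' position.  On the default density basis the ratio is
#' `(tss_count / tss_window_len) / (body_count / body_window_len)`; the
#' per-sample size factor scales both terms identically and cancels.
#' Genes with zero body-window reads are excluded (an infinite ratio is
#' uninformative); their number is reported via the `n_excluded`
#' attribute and a message.
#'
#' @param genes Gene tibble (typically from [tr_gene_set()]).
#' @param tags Tag tibble for one sample.
#' @param size_factor Size factor (kept for interface symmetry; cancels).
#' @param cfg A [pausing_config()].
#' @param chrom_sizes Optional chromosome sizes.
#' @return Tibble (`gene_id`, `tss_count`, `body_count`, `tr`) for
#'   retained genes, with attribute `n_excluded`.
#' @export
traveling_ratio <- function(genes, tags, size_factor = 1,
                            cfg = pausing_config(), chrom_sizes = NULL) {
  if (size_factor <= 0) abort("size_factor must be positive")
  tssw <- tss_window(genes, cfg$tss_up_bp, cfg$tss_down_bp, chrom_sizes)
  bodyw <- suppressMessages(
    body_window(genes, cfg$body_from_bp, cfg$body_to_bp, chrom_sizes))
  tss_cnt <- count_tags(tags, tssw, mode = "overlap", extension_bp = 0L)
  body_cnt <- count_tags(tags, bodyw, mode = "overlap", extension_bp = 0L)
  tss_len <- tssw$end - tssw$start
  body_len <- bodyw$end - bodyw$start
  tr <- if (cfg$basis == "density") {
    (tss_cnt / tss_len) / (body_cnt / body_len)
  } else {
    tss_cnt / body_cnt
  }
  out <- tibble(gene_id = genes$gene_id, tss_count = tss_cnt,
                body_count = body_cnt, tr = tr)
  excluded <- !is.finite(out$tr) | out$body_count == 0
  if (any(excluded)) {
    inform(paste0(sum(excluded),
                  " gene(s) with zero body-window reads excluded from the traveling ratio"))
  }
  out <- out[!excluded, , drop = FALSE]
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' ECDF support points of a traveling-ratio cohort
#'
#' @param tr_table Output of [traveling_ratio()].
#' @return Tibble (`tr`, `ecdf`) of sorted values and cumulative
#'   fractions, ready for cumulative-curve plotting.
#' @export
tr_ecdf <- function(tr_table) {
  v <- sort(tr_table$tr)
  tibble(tr = v, ecdf = seq_along(v) / length(v))
}

#' Compare two traveling-ratio cohorts
#'
#' Two-sample KS test on the per-gene traveling ratios of two conditions,
#' plus cohort summaries.
#'
#' @param tr_a,tr_b Outputs of [traveling_ratio()] for the two cohorts.
#' @param labels Length-2 character vector naming the cohorts.
#' @return List of class `tr_comparison`: `ks` (a `ks_result`), `summary`
#'   (tibble with n and median TR per cohort), and the two ECDF tables.
#' @export
tr_compare <- function(tr_a, tr_b, labels = c("WT", "KO")) {
  ks <- ks_two_sample(tr_a$tr, tr_b$tr)
  structure(list(
    ks = ks,
    summary = tibble(cohort = labels,
                     n = c(nrow(tr_a), nrow(tr_b)),
                     median_tr = c(median(tr_a$tr), median(tr_b$tr))),
    ecdf = setNames(list(tr_ecdf(tr_a), tr_ecdf(tr_b)), labels)),
    class = "tr_comparison")
}

#' @export
print.tr_comparison <- function(x, ...) {
  print(x$summary)
  print(x$ks)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tr_comparison <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.tr_comparison <- function(x, ...) {
  tibble(D = x$ks$D, p_value = x$ks$p_value,
         n = x$ks$n, m = x$ks$m, method = x$ks$method)
}
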