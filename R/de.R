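# Bookkeeping over externally produced differential-expression tables:
# up/down classification at the standard thresholds (padj <= 0.05,
# |log2FC| >= 1), cumulative fold-change bins, set overlaps, and
# cross-study log2FC correlation.  The DE model fit itself is consumed
# as an input table, never refit here.

#' Classify DE records as up- or down-regulated
#'
#' A record is `up` when `log2fc >= min_abs_log2fc` and
#' `padj <= padj_max`, `down` when `log2fc <= -min_abs_log2fc` and
#' `padj <= padj_max` (boundaries inclusive), otherwise `ns`.  Records
#' with missing `padj` are skipped and counted in the `n_skipped`
#' attribute.
#'
#' @param records DE tibble (already expression-filtered, e.g. by
#'   [filter_expressed()]).
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @param min_abs_log2fc Absolute log2 fold-change threshold (default 1).
#' @return `records` with a `direction` column (`up`/`down`/`ns`),
#'   missing-padj rows dropped; attribute `n_skipped`.
#' @export
classify_de <- function(records, padj_max = 0.05, min_abs_log2fc = 1) {
  skipped <- is.na(records$padj)
  out <- records[!skipped, , drop = FALSE]
  out$direction <- case_when(
    out$padj <= padj_max & out$log2fc >= min_abs_log2fc ~ "up",
    out$padj <= padj_max & out$log2fc <= -min_abs_log2fc ~ "down",
    TRUE ~ "ns")
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Up- and down-regulated gene-id sets
#' @param classified Output of [classify_de()].
#' @return List with elements `up` and `down` (character vectors).
#' @export
de_sets <- function(classified) {
  list(up = classified$gene_id[classified$direction == "up"],
       down = classified$gene_id[classified$direction == "down"])
}

#' Cumulative fold-change bin counts
#'
#' For each threshold in `fold_bins`, counts genes with
#' `padj <= padj_max` and linear fold change `2^|log2fc| >= bin`.  Bins
#' are cumulative: a 34-fold gene counts in the 2, 4, 8 and 32 bins.
#'
#' @param records DE tibble.
#' @param fold_bins Strictly increasing fold thresholds, all > 1
#'   (default `c(2, 4, 8, 32, 64, 128, 256)`).
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @return Tibble (`fold_min`, `n_genes`), counts non-increasing.
#' @export
fold_bin_counts <- function(records, fold_bins = c(2, 4, 8, 32, 64, 128, 256),
                            padj_max = 0.05) {
  if (is.unsorted(fold_bins, strictly = TRUE) || any(fold_bins <= 1)) {
    abort("fold_bins must be strictly increasing and all > 1")
  }
  keep <- !is.na(records$padj) & records$padj <= padj_max
  fold <- 2^abs(records$log2fc[keep])
  tibble(fold_min = fold_bins,
         n_genes = vapply(fold_bins, function(b) sum(fold >= b), integer(1)))
}

#' Overlap of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return Tibble (`only_a`, `shared`, `only_b`) of counts, as in a
#'   two-set Venn diagram.
#' @export
overlap_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- length(intersect(set_a, set_b))
  tibble(only_a = length(set_a) - shared, shared = shared,
         only_b = length(set_b) - shared)
}

#' Pearson correlation of log2 fold changes across two studies
#'
#' @param table_a,table_b DE tibbles with `gene_id` and `log2fc`.
#' @return Pearson r over genes present in both tables with finite
#'   log2fc; errors with fewer than 3 shared genes.
#' @export
log2fc_correlation <- function(table_a, table_b) {
  paired <- inner_join(table_a[, c("gene_id", "log2fc")],
                       table_b[, c("gene_id", "log2fc")],
                       by = "gene_id", suffix = c("_a", "_b")) |>
    filter(is.finite(.data$log2fc_a), is.finite(.data$log2fc_b))
  if (nrow(paired) < 3) {
    abort("fewer than 3 shared genes with finite log2fc; correlation undefined")
  }
  cor(paired$log2fc_a, paired$log2fc_b, method = "pearson")
}

#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Thin wrapper over [stats::p.adjust()] so synthetic fixtures need no
#' external DE fitter.
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")
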