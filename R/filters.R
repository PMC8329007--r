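# Expression-based gene filters.  Expression is measured as normalized
# reads per kb of median transcript length (base-median count divided by
# median_tx_len_kb), and thresholds are strict inequalities.

#' Filter DE records to expressed genes
#'
#' A gene counts as expressed when its base-median normalized count per kb
#' of median transcript length strictly exceeds `min_density` (default 10
#' normalized reads per kb).
#'
#' @param records DE tibble with `gene_id` and `base_median`.
#' @param genes Gene tibble supplying `median_tx_len_kb`; every record's
#'   gene must be annotated.
#' @param min_density Expression threshold, normalized reads per kb
#'   (strict; default 10).
#' @return The expressed subset of `records`, with an `expr_density`
#'   column added.
#' @export
filter_expressed <- function(records, genes, min_density = 10) {
  if (min_density <= 0) abort("min_density must be positive")
  missing <- setdiff(records$gene_id, genes$gene_id)
  if (length(missing)) {
    abort(paste0("DE records for genes absent from the annotation: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) " ..."))
  }
  out <- left_join(records, genes[, c("gene_id", "median_tx_len_kb")],
                   by = "gene_id") |>
    mutate(expr_density = .data$base_median / .data$median_tx_len_kb) |>
    filter(.data$expr_density > min_density) |>
    select(-"median_tx_len_kb")
  out
}

#' Gene set eligible for the traveling-ratio statistic
#'
#' Keeps genes expressed at more than `min_expr` normalized reads per kb
#' of median transcript length and strictly longer than `min_len_bp`
#' (defaults 100 reads/kb and 1 kb).
#'
#' @param genes Gene tibble.
#' @param records DE tibble with `gene_id` and `base_median`.
#' @param min_expr Expression threshold in normalized reads per kb
#'   (strict; default 100).
#' @param min_len_bp Minimum gene span length in bp (strict; default 1000).
#' @return The eligible subset of `genes`.
#' @export
tr_gene_set <- function(genes, records, min_expr = 100, min_len_bp = 1000L) {
  expr <- left_join(genes, records[, c("gene_id", "base_median")],
                    by = "gene_id")
  expr$base_median[is.na(expr$base_median)] <- 0
  keep <- expr$base_median / expr$median_tx_len_kb > min_expr &
    (expr$end - expr$start) > min_len_bp
  genes[keep, , drop = FALSE]
}
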