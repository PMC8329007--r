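# ggplot2 views of the result tables.  Each plot_* function takes the
# tidy output of the corresponding computation and returns a ggplot.

#' Plot metagene average profiles
#'
#' @param profile Tibble from [metagene_profile()] / [average_profile()]
#'   (several samples may be row-bound).
#' @param cfg The [profile_config()] used (for axis annotation).
#' @return A ggplot.
#' @export
plot_metagene <- function(profile, cfg = profile_config()) {
  nf <- cfg$n_flank_bins
  nb <- cfg$n_body_bins
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$value,
                               colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(nf + 0.5, nf + nb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, nf + 0.5, nf + nb + 0.5, 2 * nf + nb),
      labels = c(paste0("-", cfg$flank_bp / 1000, " kb"), "TSS", "TES",
                 paste0("+", cfg$flank_bp / 1000, " kb"))) +
    ggplot2::labs(x = NULL, y = "normalized coverage / bp",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot TSS-centered average profiles
#'
#' @param profile Tibble from [tss_profile()].
#' @return A ggplot.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset_bp, y = .data$value,
                               colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "normalized coverage / bp", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative traveling-ratio curves
#'
#' @param x A `tr_comparison` from [tr_compare()].
#' @return A ggplot of the two cohort ECDFs on a log10 x axis, annotated
#'   with the KS maximal distance and p-value.
#' @export
plot_tr_ecdf <- function(x) {
  df <- purrr::imap(x$ecdf, function(e, lab) mutate(e, cohort = lab)) |>
    bind_rows()
  lab <- sprintf("max dist = %.3f\np = %.3g", x$ks$D, x$ks$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$ecdf,
                                   colour = .data$cohort)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::annotate("text", x = Inf, y = 0.05, hjust = 1.05, vjust = 0,
                      label = lab, size = 3) +
    ggplot2::labs(x = "traveling ratio", y = "cumulative fraction of genes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tr_comparison <- function(object, ...) plot_tr_ecdf(object)

#' Plot cumulative fold-change bin counts
#'
#' @param bins Tibble from [fold_bin_counts()] (optionally with a
#'   `group` column to dodge several comparisons).
#' @return A ggplot bar chart.
#' @export
plot_fold_bins <- function(bins) {
  mapping <- if ("group" %in% names(bins)) {
    ggplot2::aes(x = factor(.data$fold_min), y = .data$n_genes,
                 fill = .data$group)
  } else {
    ggplot2::aes(x = factor(.data$fold_min), y = .data$n_genes)
  }
  ggplot2::ggplot(bins, mapping) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "|fold change| at least", y = "genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
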