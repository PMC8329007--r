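# The two cohort-comparison tests the pipeline reports: the two-sided
# Wilcoxon rank-sum test with continuity correction (density
# distributions) and the two-sample Kolmogorov-Smirnov test (traveling
# ratio ECDFs).  Both delegate to the stats implementations; the wrappers
# fix the exact-vs-asymptotic policy and return tidy-able results.

new_test_result <- function(class, ...) {
  structure(list(...), class = c(class, "chipmetrics_test"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when `length(x) * length(y) <= 64`
#' and the pooled data are tie-free, otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return A `rank_sum_result` with `statistic` (W), `p_value`, `n`, `m`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n <- length(x); m <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    # degenerate: every value identical, no evidence of a shift
    return(new_test_result("rank_sum_result", statistic = n * m / 2,
                           p_value = 1, n = n, m = m, method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n * m <= 64) && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  new_test_result("rank_sum_result",
                  statistic = unname(ht$statistic),
                  p_value = min(1, ht$p.value), n = n, m = m,
                  method = if (exact) "exact" else "normal")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the maximal absolute difference between the two empirical
#' cumulative distribution functions.  The p-value is exact (by
#' enumeration of the null distribution) when `n * m <= 10000` and the
#' samples are tie-free across each other, otherwise the asymptotic
#' Kolmogorov distribution with effective size `n * m / (n + m)` is used
#' (with a warning when ties forced the fallback).
#'
#' @param x,y Non-empty numeric samples.
#' @return A `ks_result` with `D`, `p_value`, `n`, `m`, and `method`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n <- length(x); m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n * m <= 10000) && !ties
  if ((n * m <= 10000) && ties) {
    warn("ties between samples: exact KS enumeration disabled, using the asymptotic distribution")
  }
  ht <- suppressWarnings(ks.test(x, y, exact = exact))
  new_test_result("ks_result",
                  D = unname(ht$statistic), p_value = min(1, ht$p.value),
                  n = n, m = m,
                  method = if (exact) "exact" else "asymptotic")
}

#' @export
print.chipmetrics_test <- function(x, ...) {
  stat <- if (!is.null(x$D)) c("D" = x$D) else c("W" = x$statistic)
  cat(sub("_result$", "", class(x)[1]), " test (", x$method, "): ",
      names(stat), " = ", signif(stat, 4), ", p = ", signif(x$p_value, 4),
      " (n = ", x$n, ", m = ", x$m, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chipmetrics_test <- function(x, ...) {
  tibble(statistic = if (!is.null(x$D)) x$D else x$statistic,
         p_value = x$p_value, n = x$n, m = x$m, method = x$method)
}

#' @exportS3Method generics::glance
glance.chipmetrics_test <- function(x, ...) tidy(x)
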