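# Between-sample normalization.  Two estimators, chosen per antibody:
# median-of-ratios size factors over intergenic background regions (for
# marks whose genuine signal changes globally between conditions, e.g.
# H2Bub1 upon DUB loss) and total-mapped-read factors (for Pol II /
# Ser2P, where totals are assumed comparable).

#' Count tags in a set of regions, per sample
#'
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @param tags_list Named list of tag tibbles, one per sample.
#' @param extension_bp Tag extension before counting; `0` counts the bare
#'   5' positions (the default for background-region counting).
#' @param chrom_sizes Optional chromosome sizes for extension clipping.
#' @return Integer matrix, regions x samples, rownames from `region_id`.
#' @export
region_counts <- function(regions, tags_list, extension_bp = 0L,
                          chrom_sizes = NULL) {
  if (is.null(names(tags_list)) || any(names(tags_list) == "")) {
    abort("tags_list must be a named list (one tag tibble per sample)")
  }
  region_gr <- regions_to_granges(regions[c("chrom", "start", "end")])
  counts <- vapply(tags_list, function(tags) {
    iv <- if (extension_bp > 0) {
      extend_tags(tags, extension_bp = extension_bp, chrom_sizes = chrom_sizes)
    } else {
      tibble(chrom = tags$chrom, start = tags$pos5, end = tags$pos5 + 1L)
    }
    GenomicRanges::countOverlaps(
      region_gr, regions_to_granges(iv[c("chrom", "start", "end")]),
      ignore.strand = TRUE)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(regions$region_id, names(tags_list)))
  counts
}

#' Median-of-ratios size factors from a region count matrix
#'
#' The classical median-of-ratios estimator: for every region with
#' all-positive counts, divide each sample's count by the region's
#' geometric mean across samples; a sample's size factor is the median of
#' its ratios.  Applied here to counts over large intergenic background
#' regions, it corrects sequencing-depth differences without assuming the
#' genic signal is comparable between conditions.
#'
#' @param counts Non-negative matrix, regions x samples (at least two
#'   samples), with sample names as colnames.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors_intergenic <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort("ratio-based size factors need >= 2 samples")
  if (any(counts < 0)) abort("counts must be non-negative")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    abort("no region with positive counts in every sample; cannot form ratios")
  }
  lc <- log(counts[keep, , drop = FALSE])
  log_geo <- rowMeans(lc)
  sf <- exp(apply(lc - log_geo, 2, median))
  setNames(as.numeric(sf), colnames(counts))
}

#' Size factors from total mapped reads
#'
#' Factors are each sample's total divided by the geometric mean of all
#' totals, so they are relative scalings with geometric mean 1 and no
#' sample is privileged as the reference.
#'
#' @param totals Named numeric vector of positive library sizes.
#' @return Named numeric vector of size factors.
#' @export
size_factors_total <- function(totals) {
  if (any(totals <= 0)) abort("library totals must be positive")
  sf <- totals / exp(mean(log(totals)))
  setNames(as.numeric(sf), names(totals))
}

#' Rescale a size-factor set to a reference sample
#'
#' Median-of-ratios factors are centered on the geometric mean across
#' samples.  Dividing by one sample's factor re-anchors the set so that
#' the reference sample's factor is 1; normalized densities are then
#' directly comparable across re-estimations (e.g. before and after a
#' depth change in another sample).
#'
#' @param size_factors Named numeric vector.
#' @param reference Sample name to anchor at 1.
#' @return Rescaled named numeric vector.
#' @export
rescale_factors <- function(size_factors, reference) {
  if (!reference %in% names(size_factors)) {
    abort(paste0("unknown reference sample: ", reference))
  }
  size_factors / size_factors[[reference]]
}
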