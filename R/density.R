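# Tag extension, region counting and the occupancy-density statistic:
# density = [(reads in region) / (region length in bp)] / (size factor x 1e-8).

#' Extend tags to fixed-length fragments
#'
#' Each tag becomes an interval of `extension_bp` bp running from its 5'
#' position in the read direction, clipped at chromosome bounds when
#' `chrom_sizes` is given.
#'
#' @param tags Tag tibble.
#' @param extension_bp Fragment length in bp (default 200).
#' @param chrom_sizes Optional chromosome sizes tibble for clipping.
#' @return Region tibble (`chrom`, `start`, `end`, `strand`).
#' @export
extend_tags <- function(tags, extension_bp = 200L, chrom_sizes = NULL) {
  if (extension_bp <= 0) abort("extension_bp must be positive")
  plus <- tags$strand == "+"
  start <- ifelse(plus, tags$pos5, tags$pos5 - (extension_bp - 1L))
  end <- ifelse(plus, tags$pos5 + extension_bp, tags$pos5 + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
    end <- pmin(end, unname(sz[tags$chrom]))
  }
  tibble(chrom = tags$chrom, start = as.integer(start), end = as.integer(end),
         strand = tags$strand)
}

#' Per-bp coverage of extended tags
#'
#' @param tags Tag tibble.
#' @param chrom_sizes Chromosome sizes tibble (defines track extents).
#' @param extension_bp Fragment length used for extension (default 200).
#' @return An `RleList` of per-bp coverage, one element per chromosome.
#' @export
tag_coverage <- function(tags, chrom_sizes, extension_bp = 200L) {
  iv <- extend_tags(tags, extension_bp = extension_bp,
                    chrom_sizes = chrom_sizes)
  gr <- regions_to_granges(iv[c("chrom", "start", "end")], chrom_sizes)
  GenomicRanges::coverage(gr)
}

#' Count tag signal in regions
#'
#' `overlap` mode counts tags whose extended interval intersects the
#' region by at least 1 bp; `coverage` mode returns the summed per-bp
#' overlap (total covered bases).
#'
#' @param tags Tag tibble.
#' @param regions Region tibble.
#' @param mode `"overlap"` or `"coverage"`.
#' @param extension_bp Fragment length for extension; `0` disables
#'   extension and counts bare 5' positions (overlap mode only).
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Numeric vector, one value per region.
#' @export
count_tags <- function(tags, regions, mode = c("overlap", "coverage"),
                       extension_bp = 200L, chrom_sizes = NULL) {
  mode <- match.arg(mode)
  iv <- if (extension_bp > 0) {
    extend_tags(tags, extension_bp = extension_bp, chrom_sizes = chrom_sizes)
  } else {
    tibble(chrom = tags$chrom, start = tags$pos5, end = tags$pos5 + 1L)
  }
  region_gr <- regions_to_granges(regions[c("chrom", "start", "end")])
  tag_gr <- regions_to_granges(iv[c("chrom", "start", "end")])
  if (mode == "overlap") {
    as.numeric(GenomicRanges::countOverlaps(region_gr, tag_gr,
                                            ignore.strand = TRUE))
  } else {
    hits <- GenomicRanges::findOverlaps(region_gr, tag_gr,
                                        ignore.strand = TRUE)
    ov <- IRanges::pintersect(
      region_gr[S4Vectors::queryHits(hits)],
      tag_gr[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out <- numeric(nrow(regions))
    out[as.integer(names(w))] <- as.numeric(w)
    out
  }
}

#' Normalized occupancy density of a region
#'
#' `density = (reads in region / region length in bp) / (size_factor x
#' scale_const)`, with `scale_const = 1e-8` so that typical gene-body
#' values land on a convenient scale.
#'
#' @param raw_count Reads counted in the region.
#' @param length_bp Region length in bp.
#' @param size_factor Positive per-sample size factor.
#' @param scale_const Constant in the denominator (default 1e-8).
#' @return Numeric density value(s).
#' @export
density_value <- function(raw_count, length_bp, size_factor,
                          scale_const = 1e-8) {
  if (any(size_factor <= 0)) abort("size_factor must be positive")
  (raw_count / length_bp) / (size_factor * scale_const)
}

#' Per-gene occupancy densities across samples
#'
#' Counts tags over each gene's full TSS..TES span, applies the density
#' formula with the sample's size factor, and keeps the same gene set in
#' every sample: genes with at least `min_reads` in at least one sample.
#'
#' @param genes Gene tibble (typically already restricted to expressed
#'   genes).
#' @param tags_list Named list of tag tibbles, one per sample.
#' @param size_factors Named numeric vector covering every sample in
#'   `tags_list`.
#' @param extension_bp Tag extension before counting (default 200; `0` to
#'   count bare 5' positions).
#' @param scale_const Density denominator constant (default 1e-8).
#' @param min_reads Inclusion floor: a gene is kept when its raw count
#'   reaches `min_reads` in at least one sample (default 1).
#' @param counting `"overlap"` (default) or `"coverage"`.
#' @param chrom_sizes Optional chromosome sizes.
#' @return Long tibble (`gene_id`, `sample`, `raw_count`, `density`), the
#'   same gene set in every sample.
#' @export
density_table <- function(genes, tags_list, size_factors,
                          extension_bp = 200L, scale_const = 1e-8,
                          min_reads = 1L, counting = "overlap",
                          chrom_sizes = NULL) {
  missing <- setdiff(names(tags_list), names(size_factors))
  if (length(missing)) {
    abort(paste0("no size factor for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  span <- genes[, c("gene_id", "chrom", "start", "end")]
  len <- span$end - span$start
  per_sample <- purrr::imap(tags_list, function(tags, sample_id) {
    cnt <- count_tags(tags, span, mode = counting,
                      extension_bp = extension_bp, chrom_sizes = chrom_sizes)
    sf <- size_factors[[sample_id]]
    tibble(gene_id = span$gene_id, sample = sample_id, raw_count = cnt,
           density = density_value(cnt, len, sf, scale_const))
  })
  out <- bind_rows(per_sample)
  keep_ids <- out |>
    group_by(.data$gene_id) |>
    summarise(keep = max(.data$raw_count) >= min_reads, .groups = "drop") |>
    filter(.data$keep)
  out |>
    filter(.data$gene_id %in% keep_ids$gene_id) |>
    arrange(match(.data$gene_id, genes$gene_id), .data$sample)
}

#' Condition-level fold change of occupancy densities
#'
#' Summarizes a KO/WT comparison as the ratio of per-gene density medians
#' (default) or means, over matched gene sets.
#'
#' @param wt,ko Numeric density vectors over the same gene set.
#' @param method `"median"` (robust, default) or `"mean"`.
#' @return The fold change ko/wt as a single number.
#' @export
fold_change_summary <- function(wt, ko, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") median else mean
  denom <- f(wt)
  if (denom == 0) abort("WT summary density is zero; fold change undefined")
  f(ko) / denom
}
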