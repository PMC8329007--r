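# Interval arithmetic on gene models and genomic regions.  IRanges does
# the heavy lifting; these helpers translate between the package's
# 0-based half-open tibbles and 1-based closed IRanges at the boundary.

regions_to_granges <- function(regions, chrom_sizes = NULL) {
  sl <- NULL
  if (!is.null(chrom_sizes)) sl <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  strand <- if ("strand" %in% names(regions)) {
    regions$strand
  } else {
    rep("*", nrow(regions))
  }
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand,
    seqlengths = sl)
}

granges_to_regions <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Strand-aware TSS coordinate of each gene
#' @param genes Gene tibble.
#' @return Integer vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}

#' Strand-aware TES coordinate of each gene
#' @param genes Gene tibble.
#' @return Integer vector of 0-based TES positions.
#' @export
gene_tes <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$end - 1L, genes$start))
}

strand_window <- function(genes, from_bp, to_bp) {
  # window [from_bp, to_bp) in transcription coordinates relative to the
  # TSS (negative = upstream).  Half-open mapping for minus-strand genes
  # shifts by one so the window length is always to_bp - from_bp.
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, tss + from_bp, tss - to_bp + 1L)
  end <- ifelse(plus, tss + to_bp, tss - from_bp + 1L)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(start), end = as.integer(end),
         strand = genes$strand)
}

clip_regions <- function(regions, chrom_sizes = NULL) {
  clipped <- regions$start < 0
  regions$start <- pmax(regions$start, 0L)
  if (!is.null(chrom_sizes)) {
    sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
    lim <- unname(sz[regions$chrom])
    clipped <- clipped | regions$end > lim
    regions$end <- pmin(regions$end, lim)
  }
  regions$clipped <- clipped
  if (any(regions$end <= regions$start)) {
    abort("window clipped to zero length; check coordinates")
  }
  regions
}

#' Promoter-proximal window around each TSS
#'
#' Strand-aware: the window covers `upstream_bp` before and
#' `downstream_bp` after the TSS in transcription orientation (the
#' traveling-ratio default is -100 to +300 bp).
#'
#' @param genes Gene tibble.
#' @param upstream_bp,downstream_bp Non-negative extents in bp.
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Region tibble with `gene_id` and a `clipped` flag.
#' @export
tss_window <- function(genes, upstream_bp = 100L, downstream_bp = 300L,
                       chrom_sizes = NULL) {
  if (upstream_bp < 0 || downstream_bp < 0) {
    abort("window extents must be non-negative")
  }
  if (upstream_bp + downstream_bp == 0) {
    abort("degenerate TSS window: upstream_bp + downstream_bp must be > 0")
  }
  clip_regions(strand_window(genes, -upstream_bp, downstream_bp), chrom_sizes)
}

#' Fixed gene-body window downstream of each TSS
#'
#' Strand-aware window `[from_tss_bp, to_tss_bp)` in transcription
#' coordinates (traveling-ratio default +300 to +2000 bp).  The window is
#' deliberately not clipped at the TES -- it is defined relative to the
#' TSS only -- but is clipped at chromosome bounds, with a flag.
#'
#' @param genes Gene tibble.
#' @param from_tss_bp,to_tss_bp Window bounds in bp downstream of the TSS;
#'   `to_tss_bp` must exceed `from_tss_bp`.
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Region tibble with `gene_id` and a `clipped` flag.
#' @export
body_window <- function(genes, from_tss_bp = 300L, to_tss_bp = 2000L,
                        chrom_sizes = NULL) {
  if (to_tss_bp <= from_tss_bp) abort("to_tss_bp must exceed from_tss_bp")
  out <- clip_regions(strand_window(genes, from_tss_bp, to_tss_bp),
                      chrom_sizes)
  past_tes <- (genes$end - genes$start) < to_tss_bp
  if (any(past_tes)) {
    inform(paste0(sum(past_tes), " gene(s) shorter than ", to_tss_bp,
                  " bp: body window extends past the TES (by design)"))
  }
  out
}

#' Drop genes with a neighbor within a flanking window
#'
#' A gene is kept iff no other gene's span intersects its span expanded by
#' `window_bp` on both sides; both members of a close pair are removed
#' (symmetric exclusion).
#'
#' @param genes Gene tibble.
#' @param window_bp Exclusion flank in bp (default 5000).
#' @return The non-neighboring subset of `genes`.
#' @export
remove_neighbors <- function(genes, window_bp = 5000L) {
  if (nrow(genes) < 2) return(genes)
  expanded <- genes
  expanded$start <- pmax(0L, genes$start - as.integer(window_bp))
  expanded$end <- genes$end + as.integer(window_bp)
  hits <- GenomicRanges::findOverlaps(
    regions_to_granges(expanded[c("chrom", "start", "end")]),
    regions_to_granges(genes[c("chrom", "start", "end")]),
    ignore.strand = TRUE)
  other <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
  crowded <- unique(S4Vectors::queryHits(hits)[other])
  genes[setdiff(seq_len(nrow(genes)), crowded), , drop = FALSE]
}

#' Select large intergenic background regions
#'
#' Computes, per chromosome, the complement of all gene spans expanded by
#' `gene_buffer_bp`, clipped to the chromosome, and keeps pieces longer
#' than `min_len_bp`.  These gene-distal regions carry only background
#' signal and anchor the between-sample normalization of antibodies whose
#' genuine signal changes globally between conditions.
#'
#' @param genes Gene tibble.
#' @param chrom_sizes Chromosome sizes tibble; must cover every gene chrom.
#' @param min_len_bp Minimum retained length in bp (strictly greater;
#'   default 100000, matching "larger than 100 kb").
#' @param gene_buffer_bp Distance from any gene required to count as
#'   gene-distal (default 10000).
#' @return Unstranded region tibble (`region_id`, `chrom`, `start`,
#'   `end`), disjoint and sorted.
#' @export
select_intergenic <- function(genes, chrom_sizes, min_len_bp = 100000L,
                              gene_buffer_bp = 10000L) {
  if (min_len_bp <= 0) abort("min_len_bp must be positive")
  if (gene_buffer_bp < 0) abort("gene_buffer_bp must be non-negative")
  missing_chrom <- setdiff(unique(genes$chrom), chrom_sizes$chrom)
  if (length(missing_chrom)) {
    abort(paste0("chrom_sizes lacks: ", paste(missing_chrom, collapse = ", ")))
  }
  buffered <- genes
  buffered$start <- pmax(0L, genes$start - as.integer(gene_buffer_bp))
  buffered$end <- genes$end + as.integer(gene_buffer_bp)
  gr <- regions_to_granges(buffered[c("chrom", "start", "end")], chrom_sizes)
  gr <- GenomicRanges::trim(gr)
  gaps <- GenomicRanges::gaps(gr)
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  out <- granges_to_regions(gaps)
  out <- out[out$end - out$start > min_len_bp, , drop = FALSE]
  out <- arrange(out, .data$chrom, .data$start)
  out$region_id <- sprintf("intergenic_%04d", seq_len(nrow(out)))
  select(out, "region_id", "chrom", "start", "end")
}
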