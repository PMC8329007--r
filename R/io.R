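# Readers and writers for the plain-text genomic formats the pipeline
# touches: BED6 tag files, BED gene annotation, GTF, chrom.sizes,
# bedGraph, and the TSV tables (counts, size factors, DE results).

read_delim_ws <- function(path) {
  # BED-family files are whitespace-delimited in the wild; fread copes with
  # both tabs and spaces and is fast on multi-million-line tag files.
  if (file.size(path) == 0) return(tibble())
  dt <- data.table::fread(path, header = FALSE, sep = "auto",
                          stringsAsFactors = FALSE, data.table = FALSE,
                          blank.lines.skip = TRUE, skip = "")
  as_tibble(dt)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a whitespace-delimited file with chromosome name and
#'   length in bp.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- read_delim_ws(path)
  if (ncol(x) < 2) abort("chrom.sizes file needs two columns: chrom, size")
  out <- tibble(chrom = as.character(x[[1]]), size = as.integer(x[[2]]))
  if (any(out$size <= 0)) abort("all chromosome lengths must be positive")
  out
}

#' Write a chromosome-sizes file
#' @param chrom_sizes Tibble with `chrom` and `size`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes[, c("chrom", "size")], path, col_names = FALSE)
  invisible(path)
}

#' Read aligned tags from a BED6 file
#'
#' Each data line yields one tag with its stranded 5' position: the BED
#' `start` for plus-strand reads and `end - 1` for minus-strand reads.
#' Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a 6-column BED file.
#' @return A tibble with columns `chrom`, `pos5` (0-based) and `strand`.
#' @export
read_tag_bed <- function(path) {
  x <- read_delim_ws(path)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), pos5 = integer(), strand = character()))
  }
  meta <- grepl("^(#|track\\b|browser\\b)", x[[1]])
  x <- x[!meta, , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), pos5 = integer(), strand = character()))
  }
  if (ncol(x) < 6) abort("tag BED must have 6 columns (strand required)")
  strand <- as.character(x[[6]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    abort(paste0("unknown strand symbol '", strand[bad[1]],
                 "' in ", path, " (data line ", bad[1], ")"))
  }
  start <- as.integer(x[[2]]); end <- as.integer(x[[3]])
  if (any(start < 0) || any(end <= start)) {
    abort(paste0("malformed interval in ", path, " (data line ",
                 which(start < 0 | end <= start)[1], ")"))
  }
  tibble(chrom = as.character(x[[1]]),
         pos5 = ifelse(strand == "+", start, end - 1L),
         strand = strand)
}

#' Write tags to a BED6 file
#'
#' Reads are written with a fixed read length so that a write/read
#' round-trip preserves the (chrom, pos5, strand) multiset exactly.
#'
#' @param tags Tag tibble (`chrom`, `pos5`, `strand`).
#' @param path Output path.
#' @param read_len Read length in bp used to reconstruct the interval.
#' @param header Optional character vector of `#`-prefixed comment lines
#'   (e.g. recording a simulation seed).
#' @export
write_tag_bed <- function(tags, path, read_len = 50L, header = NULL) {
  start <- ifelse(tags$strand == "+", tags$pos5,
                  pmax(0L, tags$pos5 - (read_len - 1L)))
  end <- ifelse(tags$strand == "+", tags$pos5 + read_len, tags$pos5 + 1L)
  lines <- paste(tags$chrom, start, end, ".", 0L, tags$strand, sep = "\t")
  if (!is.null(header)) lines <- c(paste0("# ", sub("^#\\s*", "", header)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' Accepts BED6 or BED12; only the first six columns are used.  Gene ids
#' come from column 4 and must be unique; strand is required.
#'
#' @param path Path to the BED file.
#' @param expression Optional tibble with `gene_id` and `median_tx_len_kb`
#'   giving the median transcript length per gene in kb; when absent, the
#'   span length / 1000 is used.
#' @return A gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `median_tx_len_kb`).
#' @export
read_gene_bed <- function(path, expression = NULL) {
  x <- read_delim_ws(path)
  if (nrow(x) > 0) {
    meta <- grepl("^(#|track\\b|browser\\b)", x[[1]])
    x <- x[!meta, , drop = FALSE]
  }
  if (nrow(x) == 0) return(empty_genes())
  if (ncol(x) < 6) abort("gene BED needs at least 6 columns (strand required)")
  start <- suppressWarnings(as.integer(x[[2]]))
  end <- suppressWarnings(as.integer(x[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    abort(paste0("malformed gene record in ", path, " (data line ", bad[1],
                 "): need 0 <= start < end"))
  }
  strand <- as.character(x[[6]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    abort(paste0("gene without usable strand in ", path,
                 " (data line ", bad[1], ")"))
  }
  genes <- tibble(gene_id = as.character(x[[4]]), chrom = as.character(x[[1]]),
                  start = start, end = end, strand = strand)
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicated gene ids: ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                       collapse = ", ")))
  }
  attach_tx_len(genes, expression)
}

#' Read gene models from a GTF file
#'
#' GTF is 1-based closed; coordinates are converted to the package's
#' 0-based half-open convention on input.  `gene` feature rows are used
#' when present, otherwise the per-`gene_id` range over all features.
#'
#' @inheritParams read_gene_bed
#' @return A gene tibble.
#' @export
read_gene_gtf <- function(path, expression = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) abort("GTF lacks a gene_id attribute")
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  if (any(!as.character(df$strand) %in% c("+", "-"))) {
    abort("gene without usable strand in GTF")
  }
  genes <- df |>
    group_by(.data$gene_id) |>
    summarise(chrom = as.character(first(.data$seqnames)),
              start = min(.data$start) - 1L, # 1-based -> 0-based half-open
              end = max(.data$end),
              strand = as.character(first(.data$strand)),
              .groups = "drop") |>
    select("gene_id", "chrom", "start", "end", "strand")
  attach_tx_len(genes, expression)
}

#' Read gene annotation, dispatching on format
#'
#' @inheritParams read_gene_bed
#' @param format `"bed"`, `"gtf"`, or `"auto"` (by file extension).
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf"),
                            expression = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  switch(format,
         bed = read_gene_bed(path, expression),
         gtf = read_gene_gtf(path, expression))
}

empty_genes <- function() {
  tibble(gene_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), median_tx_len_kb = double())
}

attach_tx_len <- function(genes, expression) {
  if (is.null(expression)) {
    genes$median_tx_len_kb <- (genes$end - genes$start) / 1000
  } else {
    genes <- left_join(genes,
                       expression[, c("gene_id", "median_tx_len_kb")],
                       by = "gene_id")
    miss <- is.na(genes$median_tx_len_kb)
    genes$median_tx_len_kb[miss] <- (genes$end - genes$start)[miss] / 1000
  }
  if (any(genes$median_tx_len_kb <= 0)) {
    abort("median_tx_len_kb must be positive for every gene")
  }
  genes
}

#' Write gene models as BED6
#' @param genes Gene tibble.
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                   genes$strand, sep = "\t"), path)
  invisible(path)
}

#' Write unstranded regions as BED3
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @export
write_region_bed <- function(regions, path) {
  writeLines(paste(regions$chrom, regions$start, regions$end, sep = "\t"),
             path)
  invisible(path)
}

#' Write a depth- and fragment-normalized bedGraph coverage track
#'
#' Tags are extended to `fragment_len` bp in the read direction, per-bp
#' coverage is computed, and values are scaled by
#' `target_total / total_reads` so that libraries of different depth are
#' directly comparable (the conventional "10 million reads, 100 bp
#' fragments" browser normalization).
#'
#' @param tags Tag tibble.
#' @param chrom_sizes Chromosome sizes tibble.
#' @param path Output path.
#' @param total_reads Library size used for scaling; defaults to
#'   `nrow(tags)`.  Must be positive.
#' @param target_total Depth every track is scaled to (default 1e7 reads).
#' @param fragment_len Extension length in bp (default 100).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(tags, chrom_sizes, path, total_reads = NULL,
                           target_total = 1e7, fragment_len = 100L) {
  total_reads <- total_reads %||% nrow(tags)
  if (is.null(total_reads) || total_reads == 0) {
    abort("total_reads is zero: cannot scale an empty library")
  }
  scale <- target_total / total_reads
  cov <- tag_coverage(tags, chrom_sizes, extension_bp = fragment_len)
  lines <- character()
  for (chrom in names(cov)) {
    r <- cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, head(ends, -1L))
    vals <- S4Vectors::runValue(r) * scale
    keep <- vals != 0
    if (!any(keep)) next
    lines <- c(lines, paste(chrom, starts[keep], ends[keep],
                            sprintf("%.12g", vals[keep]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- read_delim_ws(path)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = double()))
  }
  meta <- grepl("^(#|track\\b|browser\\b)", x[[1]])
  x <- x[!meta, , drop = FALSE]
  tibble(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
         end = as.integer(x[[3]]), value = as.numeric(x[[4]]))
}

#' Read a differential-expression result table
#'
#' Accepts the package's own column names (`gene_id`, `base_median`,
#' `log2fc`, `padj`) or DESeq2-style headers (`baseMedian`/`baseMean`,
#' `log2FoldChange`, `padj`).
#'
#' @param path Path to a TSV with a header line.
#' @return Tibble with `gene_id`, `base_median`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(x)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (!length(hit)) abort(paste0("DE table lacks a column among: ",
                                   paste(cands, collapse = ", ")))
    hit[1]
  }
  tibble(gene_id = as.character(x[[pick(c("gene_id", "gene", "id"))]]),
         base_median = as.numeric(x[[pick(c("base_median", "baseMedian",
                                            "baseMean"))]]),
         log2fc = as.numeric(x[[pick(c("log2fc", "log2FoldChange"))]]),
         padj = as.numeric(x[[pick(c("padj", "p_adj", "adj_pvalue"))]]))
}

#' Read a region-by-sample count matrix from TSV
#'
#' First column is the region id; remaining columns are samples.
#' @param path Path to the TSV (header line with sample names).
#' @return Integer matrix with region ids as rownames.
#' @export
read_count_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(x[[1]])
  m
}

#' Write a sample-to-size-factor table
#' @param size_factors Named numeric vector of size factors.
#' @param path Output path.
#' @export
write_size_factors <- function(size_factors, path) {
  readr::write_tsv(tibble(sample = names(size_factors),
                          size_factor = unname(size_factors)), path)
  invisible(path)
}
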