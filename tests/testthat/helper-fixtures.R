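# In-code fixtures shared across test files.

make_genes <- function(...) {
  g <- tibble::tribble(...)
  if (!"median_tx_len_kb" %in% names(g)) {
    g$median_tx_len_kb <- (g$end - g$start) / 1000
  }
  g
}

one_gene <- function(start = 20000L, end = 30000L, strand = "+",
                     chrom = "chr1", gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand,
                 median_tx_len_kb = (end - start) / 1000)
}

sizes_for <- function(genes, pad = 50000L) {
  genes |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(size = max(end) + pad, .groups = "drop")
}

# plus-strand tags with 5' positions on a regular grid
grid_tags <- function(from, to, by = 10L, chrom = "chr1", strand = "+") {
  pos <- seq(from, to, by = by)
  tibble::tibble(chrom = chrom, pos5 = as.integer(pos), strand = strand)
}

tags_at <- function(pos, strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos5 = as.integer(pos),
                 strand = rep_len(strand, length(pos)))
}

# mirror a genome around position `len`: coordinates reflect, strands flip
mirror_genes <- function(genes, len) {
  tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = len - genes$end, end = len - genes$start,
                 strand = ifelse(genes$strand == "+", "-", "+"),
                 median_tx_len_kb = genes$median_tx_len_kb)
}

mirror_tags <- function(tags, len) {
  tibble::tibble(chrom = tags$chrom, pos5 = len - 1L - tags$pos5,
                 strand = ifelse(tags$strand == "+", "-", "+"))
}
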