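# Independent oracles, kept deliberately naive: exhaustive enumeration
# for the rank tests, per-bp set arithmetic for interval operations.

# Two-sided Mann-Whitney p by enumeration of all label assignments of the
# pooled (tie-free) values; symmetric-tail formulation.
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x); m <- length(y)
  u_of <- function(xs, ys) {
    sum(rank(c(xs, ys))[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  u_obs <- u_of(x, y)
  center <- n * m / 2
  combos <- utils::combn(length(pooled), n)
  u_null <- apply(combos, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  mean(abs(u_null - center) >= abs(u_obs - center))
}

# Exact two-sample KS p (tie-free): P(D* >= D_obs) over all assignments.
enum_ks <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x); m <- length(y)
  d_of <- function(xs, ys) {
    grid <- sort(c(xs, ys))
    max(abs(ecdf(xs)(grid) - ecdf(ys)(grid)))
  }
  d_obs <- d_of(x, y)
  combos <- utils::combn(length(pooled), n)
  d_null <- apply(combos, 2, function(idx) {
    d_of(pooled[idx], pooled[-idx])
  })
  list(D = d_obs, p = mean(d_null >= d_obs - 1e-12))
}

# Per-bp complement of buffered gene spans on one chromosome.
bp_intergenic <- function(genes, chrom_len, buffer, min_len) {
  occupied <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(genes))) {
    s <- max(0L, genes$start[i] - buffer)
    e <- min(chrom_len, genes$end[i] + buffer)
    if (e > s) occupied[(s + 1):e] <- TRUE
  }
  r <- rle(occupied)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  keep <- !r$values & (ends - starts) > min_len
  tibble::tibble(start = starts[keep], end = ends[keep])
}
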