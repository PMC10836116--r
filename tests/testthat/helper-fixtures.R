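# Shared fixtures built in code (no files on disk).

ZT6_TIMES <- c(2, 6, 10, 14, 18, 22)

# a minimal sample sheet: one condition group of 5 replicates
one_group_samples <- function(lib = 1e6, condition = "ZT2") {
  data.table::data.table(
    sample_id = sprintf("%s_rep%d", condition, 1:5),
    condition = condition, replicate = 1:5,
    library_size = as.integer(rep_len(lib, 5)))
}

# build a pac_set directly from a count matrix (bypasses clustering)
pac_set_from_counts <- function(counts, chrom = "chr1", strand = "+") {
  n <- nrow(counts)
  info <- data.table::data.table(
    pac_id = rownames(counts) %||% sprintf("PAC%06d", seq_len(n)),
    chrom = chrom, strand = strand,
    start = seq_len(n) * 100L, end = seq_len(n) * 100L,
    summit = seq_len(n) * 100L)
  info$pac_id <- if (is.null(rownames(counts))) info$pac_id else rownames(counts)
  structure(list(info = info, counts = counts, norm_counts = NULL),
            class = "pac_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-sided KS distance against U(0,1): positive values of
# sup_x (ecdf(x) - x) detect anti-conservative p-values
ks_dplus <- function(p) {
  s <- sort(p)
  max(seq_along(s) / length(s) - s)
}

ks_crit_one_sided <- function(n, alpha = 0.001) sqrt(log(1 / alpha) / (2 * n))

# absolute circular difference in hours
circ_err <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# independent O(n^2) Kendall tau-b oracle (pair counting)
tau_b_oracle <- function(x, y) {
  n <- length(x)
  s <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    s <- s + dx * dy
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  s / den
}
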