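#' Read GMT-format gene sets
#' @param path GMT file: set name, description, then gene ids, tab-separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set: upper-tail hypergeometric p = P(X >= k) with universe
#' size N, set size K (after restriction to the universe), query size n, and
#' overlap k; enrichment ratio (k/n)/(K/N); Benjamini-Hochberg FDR across
#' sets; pass iff FDR <= \code{fdr_threshold} (inclusive).
#'
#' @param query character vector of gene ids; genes outside the universe are
#'   dropped with a warning.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable gene ids.
#' @param fdr_threshold FDR gate (default 0.05).
#' @return data.table: set_name, set_size, overlap, enrichment_ratio, p,
#'   fdr, pass.
#' @export
hypergeom_ora <- function(query, sets, universe, fdr_threshold = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after restriction to universe")
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(
      set_name = nm, set_size = K, overlap = k,
      enrichment_ratio = if (K > 0) (k / n) / (K / N) else NA_real_,
      p = p)
  })
  out <- data.table::rbindlist(res)
  out[, fdr := p.adjust(p, method = "BH")]
  out[, pass := fdr <= fdr_threshold]
  out[]
}
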