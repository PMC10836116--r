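#' @import data.table
#' @importFrom stats pchisq pf pnorm phyper dhyper rnbinom rnorm runif
#'   median mad density approx optimize dcauchy dnorm var sd rbinom
#'   p.adjust setNames qnorm quantile
#' @importFrom utils write.table read.table head tail packageVersion
NULL

# Derive a reproducible child seed from a parent seed and a stage tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# Write a TSV with '#' comment lines documenting units/conventions.
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, skip = "#" , data.table = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a string (tools::md5sum is file-based)
md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}

# Circular mean of phases (hours) on a circle of the given period.
circular_mean_phase <- function(phases_h, period_h) {
  theta <- 2 * pi * phases_h / period_h
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  (m * period_h / (2 * pi)) %% period_h
}

# Signed circular difference a - b in hours, in (-period/2, period/2].
circular_diff_h <- function(a, b, period_h) {
  d <- (a - b) %% period_h
  ifelse(d > period_h / 2, d - period_h, d)
}
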