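#' Read preprocessing parameters
#'
#' Defaults mirror the standard 3'-tag read-cleaning recipe: keep a read if
#' at least \code{min_frac} of its bases have Phred quality >= \code{min_q}
#' (boundary inclusive on both counts), trim 5' T-rich artifact sequence, and
#' retain trimmed reads of at least \code{min_len} bp.
#'
#' The T-rich trim is a deterministic two-phase rule: (1) drop all leading
#' T; (2) if at least \code{t_window_min} of the next \code{t_window} bases
#' are T, drop through the last T among them and return to (1); otherwise
#' stop. It removes homopolymer T runs and interrupted T-rich stretches and
#' provably terminates (each pass consumes at least one base).
#'
#' @param min_q minimum Phred score counted as "good" (default 10).
#' @param min_frac minimum fraction of good bases (default 0.5).
#' @param min_len minimum post-trim read length kept (default 16).
#' @param t_window lookahead window of the T-rich rule (default 4).
#' @param t_window_min minimum number of T in the window to keep trimming
#'   (default 3).
#' @return list of class "preprocess_params".
#' @export
preprocess_params <- function(min_q = 10L, min_frac = 0.5, min_len = 16L,
                              t_window = 4L, t_window_min = 3L) {
  stopifnot(min_frac >= 0, min_frac <= 1, min_len >= 1, t_window >= 1,
            t_window_min >= 1, t_window_min <= t_window)
  structure(list(min_q = as.integer(min_q), min_frac = min_frac,
                 min_len = as.integer(min_len), t_window = as.integer(t_window),
                 t_window_min = as.integer(t_window_min)),
            class = "preprocess_params")
}

#' Quality filter for a single read
#'
#' A read passes iff (number of bases with quality >= min_q) / length is
#' >= min_frac. Both boundaries are inclusive, so a read with exactly 50
#' percent of bases at exactly Q10 passes under the defaults.
#'
#' @param quals integer vector of Phred scores (one per base).
#' @param params a [preprocess_params()].
#' @return logical scalar.
#' @export
quality_filter <- function(quals, params = preprocess_params()) {
  if (length(quals) == 0L) stop("empty read: quality filter is undefined")
  if (any(quals < 0)) stop("negative Phred scores")
  mean(quals >= params$min_q) >= params$min_frac
}

# Trim index: number of leading bases to remove from a base string under the
# two-phase T-rich rule. Vectorized over reads via a per-read loop on raw
# character vectors (reads are short).
t_trim_offset <- function(bases, params = preprocess_params()) {
  w <- params$t_window; wmin <- params$t_window_min
  vapply(strsplit(bases, "", fixed = TRUE), function(b) {
    n <- length(b); i <- 1L
    repeat {
      while (i <= n && b[i] == "T") i <- i + 1L          # phase 1: leading Ts
      if (i > n) break
      win <- b[i:min(n, i + w - 1L)]                      # phase 2: lookahead
      tpos <- which(win == "T")
      if (length(tpos) >= wmin) i <- i + max(tpos) else break
    }
    i - 1L
  }, integer(1))
}

#' Trim 5' T-rich sequence from a read
#'
#' Applies the two-phase rule documented in [preprocess_params()]; qualities
#' are trimmed in lockstep with bases. May return a zero-length read.
#'
#' @param bases base string over A,C,G,T,N.
#' @param quals integer vector of Phred scores, same length as bases.
#' @param params a [preprocess_params()].
#' @return list(bases =, quals =) after trimming.
#' @export
trim_5prime_t <- function(bases, quals = NULL, params = preprocess_params()) {
  stopifnot(length(bases) == 1L)
  if (!is.null(quals) && length(quals) != nchar(bases))
    stop("quals and bases have different lengths")
  k <- t_trim_offset(bases, params)
  list(bases = substring(bases, k + 1L),
       quals = if (is.null(quals)) NULL else quals[seq_along(quals) > k])
}

qual_string_to_int <- function(q) utf8ToInt(q) - 33L

#' Preprocess a FASTQ file
#'
#' Order of operations follows the upstream recipe: quality filter first
#' (on the untrimmed read), then 5' T-rich trimming, then the minimum-length
#' gate. Reads trimmed below \code{min_len} bases are dropped (a 16 bp read
#' is kept, a 15 bp read is not, under the defaults).
#'
#' @param in_path input FASTQ (plain or .gz).
#' @param out_path output FASTQ for retained reads; NULL skips writing.
#' @param params a [preprocess_params()].
#' @return list: \code{reads} (retained, trimmed read table), \code{summary}
#'   (reads_in, reads_quality_fail, reads_length_fail, reads_out,
#'   bases_trimmed), and \code{trim_offset} (per input read: bases trimmed;
#'   NA for quality-failed reads).
#' @export
preprocess_fastq <- function(in_path, out_path = NULL,
                             params = preprocess_params()) {
  reads <- if (is.data.frame(in_path)) data.table::as.data.table(in_path)
           else read_fastq(in_path)
  if (!all(c("read_id", "seq", "qual") %in% names(reads)))
    stop("malformed FASTQ input: need read_id/seq/qual")
  bad <- which(nchar(reads$seq) != nchar(reads$qual) | nchar(reads$seq) == 0L)
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1],
         " (id ", reads$read_id[bad[1]], "): seq/qual length mismatch or empty")
  n_in <- nrow(reads)
  qints <- lapply(reads$qual, qual_string_to_int)
  pass_q <- vapply(qints, quality_filter, logical(1), params = params)
  kept <- reads[pass_q]
  off <- t_trim_offset(kept$seq, params)
  kept[, seq := substring(seq, off + 1L)]
  kept[, qual := substring(qual, off + 1L)]
  long_enough <- nchar(kept$seq) >= params$min_len
  out <- kept[long_enough]
  if (!is.null(out_path)) write_fastq(out, out_path)
  trim_offset <- rep(NA_integer_, n_in)
  trim_offset[pass_q] <- as.integer(off)
  list(reads = out,
       summary = data.table::data.table(
         reads_in = n_in,
         reads_quality_fail = n_in - nrow(kept),
         reads_length_fail = nrow(kept) - nrow(out),
         reads_out = nrow(out),
         bases_trimmed = sum(off)),
       trim_offset = trim_offset)
}
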