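#' PAC calling and filtering parameters
#'
#' @param cluster_window_nt single-linkage clustering distance: sites within
#'   this many nucleotides of one another (inclusive) join one cluster
#'   (default 25).
#' @param lib_size_cutoff library-size boundary between the lenient and
#'   strict read thresholds (default 1,700,000). Libraries with
#'   \code{library_size >= lib_size_cutoff} use the stricter rule.
#' @param min_samples minimum replicates in one condition group meeting
#'   their read threshold for a cluster to be retained (default 3).
#' @param min_reads_small_lib per-sample read threshold for libraries below
#'   the cutoff (default 3).
#' @param min_reads_large_lib per-sample read threshold for libraries at or
#'   above the cutoff (default 4).
#' @param scale normalization scale: counts are rescaled to reads per
#'   \code{scale} (default 1e7).
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return list of class "filter_params".
#' @export
filter_params <- function(cluster_window_nt = 25L, lib_size_cutoff = 1700000L,
                          min_samples = 3L, min_reads_small_lib = 3L,
                          min_reads_large_lib = 4L, scale = 1e7,
                          mito_chroms = c("MT", "chrM")) {
  stopifnot(cluster_window_nt > 0, lib_size_cutoff > 0, min_samples > 0,
            min_reads_small_lib > 0, min_reads_large_lib > 0, scale > 0)
  structure(list(cluster_window_nt = as.integer(cluster_window_nt),
                 lib_size_cutoff = lib_size_cutoff,
                 min_samples = as.integer(min_samples),
                 min_reads_small_lib = as.integer(min_reads_small_lib),
                 min_reads_large_lib = as.integer(min_reads_large_lib),
                 scale = scale, mito_chroms = mito_chroms),
            class = "filter_params")
}

#' Extract cleavage-site tags from alignment records
#'
#' The inferred cleavage site of a 3'-tag is its 3'-most aligned genomic
#' base in transcript orientation: the alignment end for + strand reads, the
#' alignment start for - strand reads (WTTS-seq style reads run into the
#' poly(A) tail, so the aligner is assumed to report tags in transcript
#' orientation; \code{flip_strand} accommodates the opposite convention).
#' Non-uniquely mapped records are excluded.
#'
#' @param alignments data.frame with columns chrom, start, end, strand,
#'   sample_id, and optionally \code{unique} (logical; default TRUE).
#' @param flip_strand flip the strand of every alignment before site
#'   extraction.
#' @return data.table of aligned tags: chrom, strand, site, sample_id.
#' @export
extract_tags <- function(alignments, flip_strand = FALSE) {
  aln <- data.table::as.data.table(alignments)
  need <- c("chrom", "start", "end", "strand", "sample_id")
  if (!all(need %in% names(aln)))
    stop("alignments need columns: ", paste(need, collapse = ", "))
  if (anyNA(aln$strand) || !all(aln$strand %in% c("+", "-")))
    stop("alignment with missing or invalid strand")
  if ("unique" %in% names(aln)) aln <- aln[aln$unique == TRUE]
  if (flip_strand) aln[, strand := ifelse(strand == "+", "-", "+")]
  aln[, .(chrom, strand,
          site = as.integer(ifelse(strand == "+", end, start)), sample_id)]
}

#' Cluster cleavage sites into poly(A)-site clusters (PACs)
#'
#' Single-linkage clustering per chromosome and strand: distinct sites are
#' sorted and a new cluster starts whenever the gap to the previous site
#' exceeds \code{cluster_window_nt} ("within 25 nt" is inclusive, so sites
#' exactly 25 nt apart co-cluster). Counts aggregate tags per sample; the
#' summit is the member site with the most total reads, ties broken toward
#' the most distal site in transcript orientation.
#'
#' @param tags data.table of aligned tags (chrom, strand, site, sample_id),
#'   all samples merged.
#' @param samples sample sheet; fixes the column order of the count matrix.
#' @param params a [filter_params()].
#' @return a \code{pac_set}: list with \code{info} (pac_id, chrom, strand,
#'   start, end, summit; 1-based inclusive) and \code{counts} (integer
#'   matrix PAC x sample).
#' @export
cluster_sites <- function(tags, samples, params = filter_params()) {
  tags <- data.table::as.data.table(tags)
  w <- params$cluster_window_nt
  data.table::setorder(tags, chrom, strand, site)
  # cluster id per (chrom, strand): new cluster when gap to previous distinct
  # site exceeds w
  tags[, cluster := {
    s <- site
    new <- c(TRUE, diff(s) > w)
    cumsum(new)
  }, by = .(chrom, strand)]
  site_tot <- tags[, .N, by = .(chrom, strand, cluster, site)]
  info <- site_tot[, {
    tot <- tapply(N, site, sum)
    cand <- as.integer(names(tot)[tot == max(tot)])
    summit <- if (strand[1] == "+") max(cand) else min(cand)
    .(start = min(site), end = max(site), summit = summit)
  }, by = .(chrom, strand, cluster)]
  data.table::setorder(info, chrom, start, strand)
  info[, pac_id := sprintf("PAC%06d", .I)]
  key <- info[, .(chrom, strand, cluster, pac_id)]
  tags <- merge(tags, key, by = c("chrom", "strand", "cluster"), sort = FALSE)
  cnt <- tags[, .N, by = .(pac_id, sample_id)]
  counts <- matrix(0L, nrow = nrow(info), ncol = nrow(samples),
                   dimnames = list(info$pac_id, samples$sample_id))
  missing_s <- setdiff(unique(cnt$sample_id), samples$sample_id)
  if (length(missing_s))
    stop("tags carry sample ids absent from the sample sheet: ",
         paste(missing_s, collapse = ", "))
  counts[cbind(match(cnt$pac_id, info$pac_id),
               match(cnt$sample_id, samples$sample_id))] <- cnt$N
  info[, cluster := NULL]
  data.table::setcolorder(info, c("pac_id", "chrom", "strand", "start", "end",
                                  "summit"))
  structure(list(info = info[], counts = counts, norm_counts = NULL),
            class = "pac_set")
}

#' Library-size-adaptive PAC retention filter
#'
#' Each sample's read threshold depends on its own library size:
#' \code{min_reads_small_lib} below \code{lib_size_cutoff},
#' \code{min_reads_large_lib} at or above it. A PAC is retained iff at least
#' one condition group contains at least \code{min_samples} replicates whose
#' count meets that replicate's threshold.
#'
#' @param pacs a \code{pac_set} from [cluster_sites()].
#' @param samples sample sheet (sample_id, condition, replicate,
#'   library_size).
#' @param params a [filter_params()].
#' @return the filtered \code{pac_set}.
#' @export
filter_pacs <- function(pacs, samples, params = filter_params()) {
  stopifnot(identical(colnames(pacs$counts), samples$sample_id))
  sizes <- table(samples$condition)
  if (any(sizes != 5L))
    warning("condition group(s) without 5 replicates: ",
            paste(names(sizes)[sizes != 5L], collapse = ", "),
            "; retention rule applied with min_samples unchanged")
  thr <- ifelse(samples$library_size < params$lib_size_cutoff,
                params$min_reads_small_lib, params$min_reads_large_lib)
  meets <- sweep(pacs$counts, 2L, thr, `>=`)
  groups <- split(seq_len(nrow(samples)), samples$condition)
  ok_any <- Reduce(`|`, lapply(groups, function(ix)
    rowSums(meets[, ix, drop = FALSE]) >= params$min_samples))
  subset_pac_set(pacs, ok_any)
}

#' Remove mitochondrial PACs
#' @param pacs a \code{pac_set}.
#' @param params a [filter_params()]; \code{mito_chroms} names the
#'   mitochondrial chromosomes.
#' @return the \code{pac_set} without mitochondrial clusters.
#' @export
remove_mitochondrial <- function(pacs, params = filter_params()) {
  subset_pac_set(pacs, !(pacs$info$chrom %in% params$mito_chroms))
}

#' Normalize PAC counts to reads per 10^7
#'
#' \code{norm_count(p, s) = count(p, s) / T_s * scale} with T_s the total
#' retained-PAC count of sample s (post-filter, post-mitochondrial-removal
#' denominator). Each sample's normalized column therefore sums exactly to
#' \code{scale} whenever T_s > 0.
#'
#' @param pacs a filtered \code{pac_set}.
#' @param params a [filter_params()].
#' @return the \code{pac_set} with a \code{norm_counts} matrix added.
#' @export
normalize_pacs <- function(pacs, params = filter_params()) {
  tot <- colSums(pacs$counts)
  if (any(tot == 0))
    warning("sample(s) with zero retained reads get all-zero normalized ",
            "counts: ", paste(colnames(pacs$counts)[tot == 0], collapse = ", "))
  denom <- ifelse(tot == 0, 1, tot)
  pacs$norm_counts <- sweep(pacs$counts, 2L, denom / params$scale, `/`)
  pacs
}

subset_pac_set <- function(pacs, keep) {
  pacs$info <- pacs$info[keep]
  pacs$counts <- pacs$counts[keep, , drop = FALSE]
  if (!is.null(pacs$norm_counts))
    pacs$norm_counts <- pacs$norm_counts[keep, , drop = FALSE]
  pacs
}

#' Full PAS-calling stage
#'
#' cluster -> library-size-adaptive filter -> mitochondrial removal ->
#' per-10^7 normalization.
#'
#' @param tags merged aligned-tag table.
#' @param samples sample sheet.
#' @param params a [filter_params()].
#' @return a normalized, filtered \code{pac_set}.
#' @export
call_pas <- function(tags, samples, params = filter_params()) {
  pacs <- cluster_sites(tags, samples, params)
  pacs <- filter_pacs(pacs, samples, params)
  pacs <- remove_mitochondrial(pacs, params)
  normalize_pacs(pacs, params)
}

#' Write a PAC table as TSV
#' @param pacs a \code{pac_set} (normalized or not).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pac_table <- function(pacs, path) {
  tab <- data.table::copy(pacs$info)
  cnt <- data.table::as.data.table(pacs$counts)
  data.table::setnames(cnt, paste0("count.", colnames(pacs$counts)))
  tab <- cbind(tab, cnt)
  if (!is.null(pacs$norm_counts)) {
    nc <- data.table::as.data.table(pacs$norm_counts)
    data.table::setnames(nc, paste0("norm.", colnames(pacs$norm_counts)))
    tab <- cbind(tab, nc)
  }
  write_tsv_commented(tab, path, comments = c(
    "PAC table; coordinates 1-based inclusive",
    "count.<sample> = raw tag counts; norm.<sample> = reads per 1e7"))
}
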