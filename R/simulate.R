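#' Simulate gene models and a planted-truth PAS table
#'
#' Lays out non-overlapping genes (3 exons, 2 introns, a long terminal 3'UTR)
#' on a single chromosome and plants 1-4 poly(A) sites (PASs) per gene, drawn
#' from \code{config$pas_per_gene_probs}. The first PAS of every gene sits at
#' the 3' terminus of the longest transcript; extra (alternative) PASs fall
#' into the canonical region categories: inside the longest 3'UTR, inside an
#' internal exon, inside an intron, or downstream ("distal") of the
#' transcript end. PASs of one gene are always > 25 nt apart so that they can
#' never co-cluster. A subset of PASs is planted with a 24 h or 12 h cosinor
#' rhythm, and a subset with a sleep-deprivation log2 fold change.
#'
#' @param config a [sim_config()].
#' @param chrom_length optional chromosome length budget; an error is raised
#'   if the genes cannot fit.
#' @return list with elements \code{genes} (one row per gene: gene_id, chrom,
#'   strand, start, end, tx_end3 = genomic coordinate of the 3' terminus,
#'   cds_end, utr3_start, utr3_end), \code{exons} (gene_id, rank, start, end),
#'   and \code{truth} (one row per planted PAS: pas_id, gene_id, chrom,
#'   strand, coord, region, period in \{"24","12","none"\}, rel_amplitude,
#'   phase_h, sd_log2fc, base_mean). All coordinates 1-based inclusive.
#' @export
simulate_genome <- function(config, chrom_length = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$n_genes
  slot_len <- 12000L
  needed <- n * slot_len + 1000L
  if (!is.null(chrom_length) && chrom_length < needed)
    stop("impossible layout: ", n, " genes need ", needed,
         " nt but chrom_length is ", chrom_length)

  extra_regions <- c("utr3_internal", "internal_exon", "intron", "utr3_distal")
  extra_probs <- c(0.50, 0.15, 0.15, 0.20)

  genes <- vector("list", n)
  exons <- vector("list", n)
  truth <- vector("list", n)
  for (g in seq_len(n)) {
    slot_start <- (g - 1L) * slot_len + 1L
    strand <- sample(c("+", "-"), 1L)
    # local layout, transcript orientation left -> right
    i1 <- sample(400:900, 1L); i2 <- sample(400:900, 1L)
    utr3_len <- sample(1200:2400, 1L)
    e1 <- c(1L, 200L)
    e2 <- c(e1[2] + i1 + 1L, e1[2] + i1 + 200L)
    e3 <- c(e2[2] + i2 + 1L, e2[2] + i2 + 300L + utr3_len)
    cds_end <- e3[1] + 99L
    tx_end <- e3[2]

    k <- sample(1:4, 1L, prob = config$pas_per_gene_probs)
    regions <- "utr3_terminal"
    if (k > 1L)
      regions <- c(regions, sample(extra_regions, k - 1L, replace = TRUE,
                                   prob = extra_probs))
    # candidate positions per category, all pairwise > 25 nt apart
    cand <- list(
      utr3_internal = seq(cds_end + 101L, tx_end - 150L, by = 150L),
      internal_exon = c(e1[1] + 100L, e2[1] + 100L, e1[1] + 50L, e2[1] + 50L),
      intron        = c(e1[2] + i1 %/% 2L, e2[2] + i2 %/% 2L,
                        e1[2] + i1 %/% 2L + 60L, e2[2] + i2 %/% 2L + 60L),
      utr3_distal   = tx_end + c(300L, 800L, 1500L, 2500L, 4000L)
    )
    coords_local <- integer(k)
    coords_local[1] <- tx_end
    used <- table(factor(character(), levels = extra_regions))
    for (j in seq_len(k - 1L)) {
      reg <- regions[j + 1L]
      used[reg] <- used[reg] + 1L
      pool <- cand[[reg]]
      if (used[reg] > length(pool)) { # pool exhausted, fall back to 3'UTR grid
        reg <- "utr3_internal"; regions[j + 1L] <- reg
        used[reg] <- used[reg] + 1L
        pool <- cand[[reg]]
      }
      pos <- if (reg == "utr3_internal")
        sort(pool, decreasing = TRUE)[used[reg]] else pool[used[reg]]
      coords_local[j + 1L] <- pos
    }

    to_genomic <- function(x) {
      if (strand == "+") slot_start + x - 1L
      else slot_start + (slot_len - 1000L) - x + 1L   # reflect within slot
    }
    ex_local <- rbind(e1, e2, e3)
    ex_gen <- cbind(to_genomic(ex_local[, 1]), to_genomic(ex_local[, 2]))
    gid <- sprintf("gene%04d", g)
    exons[[g]] <- data.table::data.table(
      gene_id = gid, rank = 1:3,
      start = pmin(ex_gen[, 1], ex_gen[, 2]),
      end = pmax(ex_gen[, 1], ex_gen[, 2]))
    genes[[g]] <- data.table::data.table(
      gene_id = gid, chrom = config$chrom, strand = strand,
      start = min(exons[[g]]$start), end = max(exons[[g]]$end),
      tx_end3 = to_genomic(tx_end), cds_end = to_genomic(cds_end),
      utr3_start = min(to_genomic(cds_end + 1L), to_genomic(tx_end)),
      utr3_end = max(to_genomic(cds_end + 1L), to_genomic(tx_end)))
    truth[[g]] <- data.table::data.table(
      pas_id = sprintf("%s_p%d", gid, seq_len(k)), gene_id = gid,
      chrom = config$chrom, strand = strand,
      coord = vapply(coords_local, to_genomic, integer(1)),
      region = regions)
  }
  genes <- data.table::rbindlist(genes)
  exons <- data.table::rbindlist(exons)
  truth <- data.table::rbindlist(truth)

  # plant rhythms, sleep-deprivation effects and base means
  np <- nrow(truth)
  n24 <- round(config$frac_cycling_24 * np)
  n12 <- round(config$frac_cycling_12 * np)
  idx <- sample.int(np, n24 + n12)
  truth[, period := "none"]
  if (n24 > 0) truth[idx[seq_len(n24)], period := "24"]
  if (n12 > 0) truth[idx[n24 + seq_len(n12)], period := "12"]
  truth[, rel_amplitude := 0]
  cyc <- truth$period != "none"
  truth[cyc, rel_amplitude := runif(sum(cyc), config$rel_amplitude_range[1],
                                    config$rel_amplitude_range[2])]
  truth[, phase_h := 0]
  truth[cyc, phase_h := runif(sum(cyc), config$phase_range_h[1],
                              config$phase_range_h[2]) %% 24]
  truth[, sd_log2fc := 0]
  nsd <- round(config$frac_sd_affected * np)
  if (nsd > 0) truth[sample.int(np, nsd), sd_log2fc := config$sd_effect_log2fc]
  truth[, base_mean := exp(runif(np, log(config$base_mean_range[1]),
                                 log(config$base_mean_range[2])))]
  list(genes = genes, exons = exons, truth = truth)
}

#' Simulate a PAS x sample count matrix with planted rhythms
#'
#' Expected normalized abundance of a cycling PAS at clock hour t is
#' \code{q(t) = m * (1 + a * cos(2*pi*(t - phi)/T))} (m = base mean per 10^7
#' reads, a = relative amplitude, phi = acrophase, T = period); non-cycling
#' PASs have constant \code{q = m}. Raw counts for sample s are drawn
#' \code{NB(mean = q(t_s) * L_s / 1e7, variance = mu + alpha * mu^2)} with
#' L_s the library size. PASs with a non-zero planted \code{sd_log2fc} have
#' their mean multiplied by \code{2^sd_log2fc} in recovery (R*) conditions.
#'
#' @param config a [sim_config()].
#' @param samples sample sheet (see [make_sample_sheet()]).
#' @param truth TruthTable from [simulate_genome()].
#' @return integer matrix, rows = pas_id, columns = sample_id.
#' @export
simulate_counts <- function(config, samples, truth) {
  validate_sim_config(config)
  if (any(truth$rel_amplitude > 1))
    stop("relative amplitude > 1 would give negative means")
  set.seed(derive_seed(config$seed, "counts"))
  t_h <- condition_hour(samples$condition)
  recovery <- grepl("^R", samples$condition)
  np <- nrow(truth); ns <- nrow(samples)
  period_num <- suppressWarnings(as.numeric(truth$period)) # NA for "none"
  # q: np x ns expected abundance per 1e7
  phase_arg <- outer(seq_len(np), seq_len(ns), function(i, s)
    cos(2 * pi * (t_h[s] - truth$phase_h[i]) / period_num[i]))
  phase_arg[is.na(phase_arg)] <- 0
  q <- truth$base_mean * (1 + truth$rel_amplitude * phase_arg)
  sdmult <- outer(2^truth$sd_log2fc, as.numeric(recovery), function(f, r)
    ifelse(r > 0, f, 1))
  mu <- q * sdmult * rep(samples$library_size / 1e7, each = np)
  counts <- matrix(rnbinom(np * ns, size = 1 / config$nb_dispersion, mu = mu),
                   nrow = np, ncol = ns,
                   dimnames = list(truth$pas_id, samples$sample_id))
  counts
}

#' Simulate aligned 3'-tag records from a count matrix
#'
#' Each count c for PAS p in sample s becomes c tags whose cleavage
#' coordinate is the true coordinate plus rounded Gaussian jitter
#' (sd = \code{config$tag_jitter_sd_nt}, clamped to |jitter| <= 12 nt so
#' that planted PASs > 25 nt apart can never merge during clustering).
#'
#' @param config a [sim_config()].
#' @param truth TruthTable from [simulate_genome()].
#' @param counts matrix from [simulate_counts()].
#' @return data.table of aligned tags: chrom, strand, site (1-based cleavage
#'   coordinate), sample_id, true_pas_id (ground-truth linkage).
#' @export
simulate_tags <- function(config, truth, counts) {
  validate_sim_config(config)
  stopifnot(identical(rownames(counts), truth$pas_id))
  set.seed(derive_seed(config$seed, "tags"))
  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    return(data.table::data.table(chrom = character(), strand = character(),
                                  site = integer(), sample_id = character(),
                                  true_pas_id = character()))
  reps <- counts[nz]
  i <- rep.int(nz[, 1], reps)
  s <- rep.int(nz[, 2], reps)
  ntag <- length(i)
  jitter <- if (config$tag_jitter_sd_nt > 0)
    pmax(pmin(round(rnorm(ntag, 0, config$tag_jitter_sd_nt)), 12L), -12L)
  else integer(ntag)
  data.table::data.table(
    chrom = truth$chrom[i], strand = truth$strand[i],
    site = pmax(truth$coord[i] + as.integer(jitter), 1L),
    sample_id = colnames(counts)[s], true_pas_id = truth$pas_id[i])
}

#' Simulate a FASTQ file exercising the read-level filters
#'
#' Emits reads of 30-120 nt. A fraction \code{t_prefix_prob} carries a 5'
#' T-rich artifact prefix of 5-20 nt: runs of T interrupted by isolated
#' non-T bases (never adjacent, never within the last 3 prefix positions),
#' >= 80 percent T overall — emulating read-through into the poly(A) tail.
#' The clean insert never begins with T (the clean start is only
#' well-defined when insert and artifact are distinguishable). A fraction
#' \code{frac_low_quality} of reads draws base qualities from a low (~Q8)
#' component instead of the high (~Q30) one, so the quality filter has both
#' outcomes. The planted truth of every read is recorded.
#'
#' @param config a [sim_config()].
#' @param path optional output FASTQ path (plain text or .gz).
#' @return list with \code{reads} (data.table: read_id, seq, qual = Phred+33
#'   string) and \code{truth} (read_id, has_prefix, prefix_len, clean_start =
#'   1-based position of the first insert base, clean_len, low_quality).
#' @export
simulate_fastq <- function(config, path = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "fastq"))
  n <- config$n_fastq_reads
  bases <- c("A", "C", "G", "T")
  clean_len <- sample(30:100, n, replace = TRUE)
  has_prefix <- runif(n) < config$t_prefix_prob
  prefix_len <- ifelse(has_prefix, sample(5:20, n, replace = TRUE), 0L)
  low_q <- runif(n) < config$frac_low_quality

  # T-rich artifact: isolated non-T bases spaced >= 4 apart, never at the
  # first position or in the last 3 (the run abuts the insert), so the
  # trimmer's 3-of-4 window always carries through the whole prefix
  make_prefix <- function(len) {
    p <- rep("T", len)
    n_nont <- min(rbinom(1L, len, 0.08), floor(len * 0.2))
    if (n_nont > 0) {
      ok <- 2:(len - 3L)
      cand_order <- ok[sample.int(length(ok))]
      pos <- integer(0)
      for (cand in cand_order) {
        if (length(pos) >= n_nont) break
        if (all(abs(cand - pos) > 3L)) pos <- c(pos, cand)
      }
      p[pos] <- sample(c("A", "C", "G"), length(pos), replace = TRUE)
    }
    paste(p, collapse = "")
  }
  seqs <- character(n); quals <- character(n)
  for (r in seq_len(n)) {
    cl <- c(sample(c("A", "C", "G"), 1L),
            sample(bases, clean_len[r] - 1L, replace = TRUE))
    sq <- paste(cl, collapse = "")
    if (has_prefix[r]) sq <- paste0(make_prefix(prefix_len[r]), sq)
    L <- nchar(sq)
    qm <- if (low_q[r]) 8 else 30
    qv <- pmax(pmin(round(rnorm(L, qm, 3)), 40L), 2L)
    seqs[r] <- sq
    quals[r] <- intToUtf8(qv + 33L)
  }
  reads <- data.table::data.table(
    read_id = sprintf("read%06d", seq_len(n)), seq = seqs, qual = quals)
  truth <- data.table::data.table(
    read_id = reads$read_id, has_prefix = has_prefix,
    prefix_len = as.integer(ifelse(has_prefix, prefix_len, 0L)),
    clean_start = as.integer(ifelse(has_prefix, prefix_len, 0L)) + 1L,
    clean_len = clean_len, low_quality = low_q)
  if (!is.null(path)) write_fastq(reads, path)
  list(reads = reads, truth = truth)
}

#' Write reads to FASTQ
#' @param reads data.table with read_id, seq, qual (Phred+33 string).
#' @param path output path; ".gz" suffix writes gzip.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::BStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#' @param path FASTQ path (plain or gzip).
#' @return data.table with read_id, seq, qual (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    read_id = names(x), seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write simulated tags as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' a tag at site p is written as (p-1, p). The name field carries the sample
#' id, score is 1.
#' @param tags data.table from [simulate_tags()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.table::data.table(
    chrom = tags$chrom, start = tags$site - 1L, end = tags$site,
    name = tags$sample_id, score = 1L, strand = tags$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 tag file into aligned-tag records
#' @param path BED6 path: chrom, start, end, name = sample id, score, strand.
#' @return data.table with chrom, strand, site, sample_id.
#' @export
read_tags_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  data.table::data.table(chrom = bed$chrom, strand = bed$strand,
                         site = bed$end, sample_id = bed$name)
}

#' Write simulated gene models as GTF
#' @param sim output of [simulate_genome()].
#' @param path output GTF path.
#' @return the path, invisibly.
#' @export
write_genome_gtf <- function(sim, path) {
  ex <- merge(sim$exons, sim$genes[, c("gene_id", "chrom", "strand")],
              by = "gene_id")
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand, type = "exon", source = "apaRhythm",
    gene_id = ex$gene_id, transcript_id = paste0(ex$gene_id, ".t1"),
    exon_number = ex$rank, phase = NA_integer_)
  g <- sim$genes
  ggr <- GenomicRanges::GRanges(
    seqnames = g$chrom, ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand, type = "gene", source = "apaRhythm",
    gene_id = g$gene_id, transcript_id = NA_character_,
    exon_number = NA_integer_, phase = NA_integer_)
  # CDS feature so the 3'UTR can be derived from the GTF alone
  cds <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(ifelse(g$strand == "+", g$start, g$cds_end),
                              ifelse(g$strand == "+", g$cds_end, g$end)),
    strand = g$strand, type = "CDS", source = "apaRhythm",
    gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1"),
    exon_number = NA_integer_, phase = 0L)
  rtracklayer::export(c(ggr, gr, cds), path, format = "gtf")
  invisible(path)
}
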