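#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' data generator. The defaults describe a desk-scale version of a 3'-tag
#' (WTTS-seq style) study of rat forebrain: genes carry 1-4 poly(A) sites
#' (PASs), a minority of PASs cycle with a 24 h or 12 h period, counts are
#' negative-binomially distributed (variance = mu + alpha * mu^2), library
#' sizes straddle the 1.7M-read filtering cutoff, and recovery-from-sleep-
#' deprivation conditions multiply the mean of affected PASs by
#' \code{2^sd_effect_log2fc}.
#'
#' @param seed integer; fully determines all simulator output.
#' @param n_genes number of simulated genes.
#' @param pas_per_gene_probs probability vector over 1..4 PASs per gene.
#' @param frac_cycling_24,frac_cycling_12 fractions of PASs planted with a
#'   24 h / 12 h cosinor rhythm.
#' @param rel_amplitude_range range (low, high) of relative amplitudes in
#'   (0, 1] for cycling PASs.
#' @param phase_range_h range of planted acrophases, hours in [0, 24).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param base_mean_range range of expected counts per 10^7 reads; base
#'   means are drawn log-uniformly.
#' @param library_sizes integer vector of per-sample library sizes, recycled
#'   over the sample sheet; NULL draws them uniformly from
#'   \code{library_size_range}.
#' @param library_size_range range library sizes are drawn from when
#'   \code{library_sizes} is NULL; default straddles 1.7M reads.
#' @param sd_effect_log2fc log2 fold change applied to sleep-deprivation-
#'   affected PASs in recovery conditions.
#' @param frac_sd_affected fraction of PASs affected by sleep deprivation.
#' @param tag_jitter_sd_nt SD (nt) of the Gaussian jitter of tag cleavage
#'   coordinates around the true PAS; jitter is truncated at +/- 12 nt.
#' @param t_prefix_prob fraction of simulated FASTQ reads given a 5'
#'   T-rich artifact prefix.
#' @param frac_low_quality fraction of simulated FASTQ reads drawn from the
#'   low-quality (~Q8) component so the quality filter has both outcomes.
#' @param n_fastq_reads number of reads emitted by [simulate_fastq()].
#' @param chrom chromosome name used for all simulated genes.
#'
#' @return a list of class \code{"sim_config"}.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20)
#' sim <- simulate_genome(cfg)
#' nrow(sim$truth) >= 20
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       pas_per_gene_probs = c(0.55, 0.26, 0.12, 0.07),
                       frac_cycling_24 = 0.06,
                       frac_cycling_12 = 0.05,
                       rel_amplitude_range = c(0.2, 0.8),
                       phase_range_h = c(0, 24),
                       nb_dispersion = 0.05,
                       base_mean_range = c(20, 500),
                       library_sizes = NULL,
                       library_size_range = c(1.2e6, 2.2e6),
                       sd_effect_log2fc = 1,
                       frac_sd_affected = 0.025,
                       tag_jitter_sd_nt = 3,
                       t_prefix_prob = 0.5,
                       frac_low_quality = 0.15,
                       n_fastq_reads = 2000L,
                       chrom = "chr1") {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    pas_per_gene_probs = pas_per_gene_probs,
    frac_cycling_24 = frac_cycling_24, frac_cycling_12 = frac_cycling_12,
    rel_amplitude_range = rel_amplitude_range, phase_range_h = phase_range_h,
    nb_dispersion = nb_dispersion, base_mean_range = base_mean_range,
    library_sizes = library_sizes, library_size_range = library_size_range,
    sd_effect_log2fc = sd_effect_log2fc, frac_sd_affected = frac_sd_affected,
    tag_jitter_sd_nt = tag_jitter_sd_nt, t_prefix_prob = t_prefix_prob,
    frac_low_quality = frac_low_quality, n_fastq_reads = as.integer(n_fastq_reads),
    chrom = chrom
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  p <- cfg$pas_per_gene_probs
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("pas_per_gene_probs must be 4 non-negative probabilities summing to 1 (1e-9)")
  for (nm in c("rel_amplitude_range", "phase_range_h", "base_mean_range",
               "library_size_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2]) stop(nm, " must be an ordered (low, high) pair")
  }
  if (cfg$rel_amplitude_range[1] <= 0 || cfg$rel_amplitude_range[2] > 1)
    stop("relative amplitudes must lie in (0, 1]: a > 1 would give negative means")
  if (cfg$phase_range_h[1] < 0 || cfg$phase_range_h[2] > 24)
    stop("phase_range_h must lie in [0, 24)")
  for (nm in c("frac_cycling_24", "frac_cycling_12", "frac_sd_affected",
               "t_prefix_prob", "frac_low_quality")) {
    v <- cfg[[nm]]
    if (v < 0 || v > 1) stop(nm, " must be a fraction in [0, 1]")
  }
  if (cfg$frac_cycling_24 + cfg$frac_cycling_12 > 1)
    stop("frac_cycling_24 + frac_cycling_12 must not exceed 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$tag_jitter_sd_nt < 0) stop("tag_jitter_sd_nt must be non-negative")
  if (!is.null(cfg$library_sizes) && any(cfg$library_sizes <= 0))
    stop("library_sizes must be positive")
  cfg
}

#' Condition labels to clock hours
#'
#' Maps condition labels to the zeitgeber hour at which tissue was collected.
#' Recovery conditions after 6 h sleep deprivation ending at ZT6 map to the
#' matching clock times: R0 -> ZT6, R2 -> ZT8, R4 -> ZT10, R8 -> ZT14.
#'
#' @param condition character vector of condition labels.
#' @return numeric vector of hours in [0, 24).
#' @export
condition_hour <- function(condition) {
  map <- c(ZT2 = 2, ZT6 = 6, ZT8 = 8, ZT10 = 10, ZT14 = 14, ZT18 = 18,
           ZT22 = 22, R0 = 6, R2 = 8, R4 = 10, R8 = 14)
  h <- map[condition]
  if (anyNA(h)) stop("unknown condition label(s): ",
                     paste(unique(condition[is.na(h)]), collapse = ", "))
  unname(h)
}

#' Build the study sample sheet
#'
#' The design follows the source study: 6 circadian timepoints
#' (ZT2..ZT22, every 4 h) x 5 replicates, plus a sleep-deprivation arm
#' (R0, R2, R4, R8 and the extra undisturbed ZT8 control) x 5 replicates.
#' The ZT6/ZT10/ZT14 controls are shared between the two analyses, giving
#' 55 unique libraries. Library sizes are drawn from
#' \code{config$library_size_range} (or taken from \code{config$library_sizes})
#' and deliberately straddle the 1.7M-read filtering cutoff.
#'
#' @param config a [sim_config()].
#' @param n_replicates replicates per condition group (default 5).
#' @return data.table with columns sample_id, condition, replicate,
#'   library_size.
#' @export
make_sample_sheet <- function(config, n_replicates = 5L) {
  validate_sim_config(config)
  conditions <- c("ZT2", "ZT6", "ZT8", "ZT10", "ZT14", "ZT18", "ZT22",
                  "R0", "R2", "R4", "R8")
  sheet <- data.table::CJ(condition = conditions, replicate = seq_len(n_replicates),
                          sorted = FALSE)
  sheet[, condition := factor(condition, levels = conditions)]
  data.table::setorder(sheet, condition, replicate)
  sheet[, condition := as.character(condition)]
  sheet[, sample_id := sprintf("%s_rep%d", condition, replicate)]
  n <- nrow(sheet)
  if (!is.null(config$library_sizes)) {
    sheet[, library_size := as.integer(rep_len(config$library_sizes, n))]
  } else {
    set.seed(derive_seed(config$seed, "libsize"))
    sheet[, library_size := as.integer(round(runif(
      n, config$library_size_range[1], config$library_size_range[2])))]
  }
  data.table::setcolorder(sheet, c("sample_id", "condition", "replicate",
                                   "library_size"))
  sheet[]
}

#' Subset a sample sheet to the circadian design
#' @param samples sample sheet from [make_sample_sheet()].
#' @return the rows belonging to the 6-timepoint circadian arm.
#' @export
circadian_samples <- function(samples) {
  samples[samples$condition %in% c("ZT2", "ZT6", "ZT10", "ZT14", "ZT18", "ZT22"), ]
}

#' Subset a sample sheet to the sleep-deprivation design
#' @param samples sample sheet from [make_sample_sheet()].
#' @return rows for the 8 SD-analysis groups (R0,R2,R4,R8 and matched controls).
#' @export
sd_samples <- function(samples) {
  samples[samples$condition %in% c("R0", "R2", "R4", "R8",
                                   "ZT6", "ZT8", "ZT10", "ZT14"), ]
}
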