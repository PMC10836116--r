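test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(pas_per_gene_probs = c(0.5, 0.5, 0.1, 0)), "sum")
  expect_error(sim_config(rel_amplitude_range = c(0.5, 1.2)), "negative means")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(base_mean_range = c(10, 5)), "ordered")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("simulate_genome plants the configured PAS layout", {
  # degenerate distribution: every gene exactly one PAS, always terminal
  cfg1 <- sim_config(seed = 2, n_genes = 30,
                     pas_per_gene_probs = c(1, 0, 0, 0))
  sim1 <- simulate_genome(cfg1)
  expect_equal(nrow(sim1$truth), 30L)
  expect_true(all(sim1$truth$region == "utr3_terminal"))

  # determinism: same config twice is byte-identical
  cfg <- sim_config(seed = 7, n_genes = 50)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))

  # empirical mean PASs/gene near the distribution's expectation (1.71)
  cfg2 <- sim_config(seed = 11, n_genes = 200,
                     pas_per_gene_probs = c(0.55, 0.26, 0.12, 0.07))
  sim2 <- simulate_genome(cfg2)
  expect_lt(abs(nrow(sim2$truth) / 200 - 1.71), 0.15)

  # PASs of one gene pairwise > 25 nt apart
  gaps <- sim2$truth[, .(ok = all(diff(sort(coord)) > 25)), by = gene_id]
  expect_true(all(gaps$ok))

  # layout error is reported
  expect_error(simulate_genome(cfg2, chrom_length = 1000), "impossible layout")
})

test_that("simulate_counts follows the cosinor NB model", {
  cfg <- sim_config(seed = 3, n_genes = 5, nb_dispersion = 1e-8,
                    frac_cycling_24 = 0, frac_cycling_12 = 0,
                    frac_sd_affected = 0)
  sim <- simulate_genome(cfg)
  samples <- one_group_samples(lib = 1e7)
  # Poisson limit: var/mean -> 1 over many draws
  truth1 <- sim$truth[1]
  truth1$base_mean <- 100
  big <- do.call(rbind, replicate(2000, samples, simplify = FALSE))
  big$sample_id <- sprintf("s%05d", seq_len(nrow(big)))
  cnt <- simulate_counts(cfg, big, truth1)
  expect_lt(abs(var(as.numeric(cnt)) / mean(cnt) - 1), 0.1)

  # plug-in expectation: m=100, a=0.5, phi=6, T=24 at ZT6, library 1e7 -> 150
  truth2 <- sim$truth[1]
  truth2[, `:=`(base_mean = 100, rel_amplitude = 0.5, phase_h = 6,
                period = "24")]
  s6 <- one_group_samples(lib = 1e7, condition = "ZT6")
  many <- do.call(rbind, replicate(2000, s6, simplify = FALSE))
  many$sample_id <- sprintf("s%05d", seq_len(nrow(many)))
  cnt2 <- simulate_counts(cfg, many, truth2)
  expect_lt(abs(mean(cnt2) - 150), 1)

  # amplitude > 1 rejected
  bad <- data.table::copy(truth2)[, rel_amplitude := 1.2]
  expect_error(simulate_counts(cfg, s6, bad), "negative means")
})

test_that("null counts give amplitude estimates centered at zero", {
  cfg <- sim_config(seed = 13, n_genes = 120, frac_cycling_24 = 0,
                    frac_cycling_12 = 0, frac_sd_affected = 0)
  sim <- simulate_genome(cfg)
  samples <- make_sample_sheet(cfg)
  circ <- circadian_samples(samples)
  cnt <- simulate_counts(cfg, circ, sim$truth)
  # cosinor relative amplitude on group means: should straddle 0 tightly
  t_h <- condition_hour(circ$condition)
  gm <- sapply(split(seq_len(nrow(circ)), t_h), function(ix)
    rowMeans(cnt[, ix, drop = FALSE]))
  rel_amp <- vapply(seq_len(nrow(gm)), function(i) {
    f <- cosinor_fit(gm[i, ], sort(unique(t_h)), 24)
    f$amplitude / max(mean(gm[i, ]), 1e-9)
  }, numeric(1))
  expect_lt(median(rel_amp), 0.15)
})

test_that("simulate_tags obeys jitter contract and conservation", {
  cfg0 <- sim_config(seed = 5, n_genes = 40, tag_jitter_sd_nt = 0)
  sim <- simulate_genome(cfg0)
  samples <- make_sample_sheet(cfg0)
  cnt <- simulate_counts(cfg0, samples, sim$truth)
  tags <- simulate_tags(cfg0, sim$truth, cnt)
  # conservation: per-sample tag totals equal count column sums
  per_sample <- tags[, .N, by = sample_id]
  expect_equal(per_sample$N[match(colnames(cnt), per_sample$sample_id)],
               unname(colSums(cnt)))
  # jitter 0: every tag exactly at its true coordinate
  expect_true(all(tags$site ==
                    sim$truth$coord[match(tags$true_pas_id, sim$truth$pas_id)]))

  # zero counts -> empty tag set
  expect_equal(nrow(simulate_tags(cfg0, sim$truth, cnt * 0L)), 0L)

  # jitter sd 3: >= 99% of tags within +/- 10 nt, all within +/- 12
  cfg3 <- sim_config(seed = 5, n_genes = 40, tag_jitter_sd_nt = 3)
  tags3 <- simulate_tags(cfg3, sim$truth, cnt)
  dev <- abs(tags3$site -
               sim$truth$coord[match(tags3$true_pas_id, sim$truth$pas_id)])
  expect_gte(mean(dev <= 10), 0.99)
  expect_true(all(dev <= 12))
})

test_that("simulate_fastq plants prefixes and quality classes as stated", {
  cfg0 <- sim_config(seed = 9, t_prefix_prob = 0, n_fastq_reads = 400)
  fq0 <- simulate_fastq(cfg0)
  expect_false(any(startsWith(fq0$reads$seq, "TTT")))
  expect_true(all(!fq0$truth$has_prefix))

  cfg1 <- sim_config(seed = 9, t_prefix_prob = 1, n_fastq_reads = 400)
  fq1 <- simulate_fastq(cfg1)
  expect_true(all(fq1$truth$has_prefix))
  expect_true(all(startsWith(fq1$reads$seq, "T")))
  # prefix is >= 80% T by construction
  tfrac <- vapply(seq_len(400), function(i) {
    pre <- substr(fq1$reads$seq[i], 1, fq1$truth$prefix_len[i])
    mean(strsplit(pre, "")[[1]] == "T")
  }, numeric(1))
  expect_true(all(tfrac >= 0.8))

  # determinism + FASTQ round trip
  fq1b <- simulate_fastq(cfg1)
  expect_identical(fq1$reads, fq1b$reads)
  tf <- tempfile(fileext = ".fastq.gz")
  write_fastq(fq1$reads, tf)
  back <- read_fastq(tf)
  expect_equal(back$seq, fq1$reads$seq)
  expect_equal(back$qual, fq1$reads$qual)
})

test_that("trimmer recovers >= 95% of planted clean starts", {
  cfg <- sim_config(seed = 17, t_prefix_prob = 1, frac_low_quality = 0,
                    n_fastq_reads = 600)
  fq <- simulate_fastq(cfg)
  res <- preprocess_fastq(fq$reads)
  off <- res$trim_offset
  exact <- off == (fq$truth$clean_start - 1L)
  expect_gte(mean(exact, na.rm = TRUE), 0.95)
})
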