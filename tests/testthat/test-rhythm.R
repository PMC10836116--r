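test_that("cosinor fit recovers exact harmonic models", {
  t6 <- ZT6_TIMES
  y <- 10 + 5 * cos(2 * pi * (t6 - 6) / 24)
  r <- cosinor_fit(y, t6, 24)
  expect_equal(r$amplitude, 5, tolerance = 1e-9)
  expect_equal(r$phase_h, 6, tolerance = 1e-9)
  expect_lt(r$p, 1e-20)

  rc <- cosinor_fit(rep(7, 6), t6, 24)
  expect_equal(rc$amplitude, 0)
  expect_equal(rc$p, 1)

  expect_error(cosinor_fit(1:3, c(1, 2, 3), 24), ">= 4")
})

test_that("cosinor p equals an independent linear-model F-test", {
  set.seed(101)
  t6 <- ZT6_TIMES
  for (i in 1:25) {
    y <- 20 + 4 * cos(2 * pi * (t6 - runif(1, 0, 24)) / 24) + rnorm(6, 0, 3)
    r <- cosinor_fit(y, t6, 24)
    fit <- lm(y ~ cos(2 * pi * t6 / 24) + sin(2 * pi * t6 / 24))
    an <- anova(lm(y ~ 1), fit)
    expect_equal(r$p, an$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(r$statistic, an$F[2], tolerance = 1e-8)
  }
})

test_that("Lomb-Scargle power and tails behave as specified", {
  t6 <- ZT6_TIMES
  y <- cos(2 * pi * t6 / 24)
  r <- lomb_scargle(y, t6, 24)
  expect_equal(r$statistic, 2.5, tolerance = 1e-9)     # (n-1)/2
  # asymptotic single-frequency tail: p = exp(-P)
  ra <- lomb_scargle(y, t6, 24, null = "asymptotic")
  expect_equal(ra$p, exp(-2.5), tolerance = 1e-6)
  # exact finite-sample tail at maximal power
  expect_equal(r$p, .Machine$double.xmin)

  # invariance to shift and positive scaling
  r2 <- lomb_scargle(3 + 2 * y, t6, 24)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)
  expect_equal(r2$p, r$p)

  # constant series
  rc <- lomb_scargle(rep(4, 6), t6, 24)
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p, 1)

  # the exact null is calibrated under Gaussian noise; the asymptotic
  # exp(-P) tail is anti-conservative at n = 6
  set.seed(77)
  Y <- matrix(rnorm(4000 * 6), 4000)
  pe <- apaRhythm:::ls_mat(Y, t6, 24)$p
  pa <- apaRhythm:::ls_mat(Y, t6, 24, null = "asymptotic")$p
  expect_lt(ks_dplus(pe), ks_crit_one_sided(4000))
  expect_gt(ks_dplus(pa), ks_crit_one_sided(4000))
})

test_that("JTK tau matches a pair-count oracle and has an exact null", {
  t6 <- ZT6_TIMES
  # tau computation vs independent O(n^2) oracle, with and without ties
  set.seed(55)
  ref <- cos(2 * pi * (t6 - 1) / 24)
  for (i in 1:200) {
    y <- if (i %% 2) rnorm(6) else sample(1:3, 6, replace = TRUE)
    jm <- apaRhythm:::jtk_mat(matrix(y, 1), t6, 24, phase_grid_h = 24)
    # single lag 0: compare against oracle on the lag-0 reference
    ref0 <- cos(2 * pi * t6 / 24)
    expect_equal(jm$statistic[1], tau_b_oracle(y, ref0) |>
                   (\(x) if (is.na(x)) 0 else x)(), tolerance = 1e-12)
  }

  # null distribution sums to 1 and matches brute force (see acceptance too)
  nd <- jtk_null_distribution(c(5, 2, 4, 1, 6, 3), ref)
  expect_equal(sum(nd$prob), 1, tolerance = 1e-12)
  expect_equal(sum(nd$prob[abs(nd$tau) > 1 - 1e-9]), 2 / 720,
               tolerance = 1e-12)

  # a series equal to the reference ranks gives tau 1 at that lag
  y1 <- rank(ref)
  j1 <- jtk_cycle(y1, t6, 24)
  expect_equal(abs(j1$statistic), 1, tolerance = 1e-12)

  # all-tied series: p = 1
  jt <- jtk_cycle(rep(3, 6), t6, 24)
  expect_equal(jt$p, 1)

  # Bonferroni cap: p never exceeds 1
  set.seed(9)
  ps <- replicate(50, jtk_cycle(rnorm(6), t6, 24)$p)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("Fisher integration matches the chi-square closed form", {
  mk <- function(p, phase = 3) list(method = "LS", p = p, phase_h = phase,
                                    amplitude = 1, statistic = 0)
  # k = 1 identity
  one <- integrate_meta(list(mk(0.2)), 24)
  expect_equal(one$meta_p, 0.2, tolerance = 1e-12)
  # k = 3 closed form
  m <- integrate_meta(list(mk(0.05), mk(0.05), mk(0.05)), 24)
  expect_equal(m$meta_p, pchisq(-6 * log(0.05), 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical phases pass through exactly
  expect_equal(m$meta_phase_h, 3, tolerance = 1e-9)
  # p = 0 is clamped, not an error
  z <- integrate_meta(list(mk(0)), 24)
  expect_gt(z$meta_p, 0)
})

test_that("build_trials produces the rotation Latin square", {
  samples <- circadian_samples(make_sample_sheet(sim_config(seed = 1)))
  tr <- build_trials(samples)
  expect_length(tr, 5L)
  # trial 1 assigns replicates (1,2,3,4,5,1) to ZT2..ZT22
  expect_equal(tr[[1]], c("ZT2_rep1", "ZT6_rep2", "ZT10_rep3", "ZT14_rep4",
                          "ZT18_rep5", "ZT22_rep1"))
  # Latin square: per slot, each replicate used exactly once across trials
  slot_reps <- sapply(1:6, function(i)
    vapply(tr, function(x) sub("^.*_rep", "", x[i]), character(1)))
  expect_true(all(apply(slot_reps, 2, function(x)
    setequal(x, as.character(1:5)))))

  # seeded_random is reproducible and complete
  a <- build_trials(samples, scheme = "seeded_random", seed = 42)
  b <- build_trials(samples, scheme = "seeded_random", seed = 42)
  expect_identical(a, b)
  for (i in 1:6)
    expect_setequal(vapply(a, `[`, character(1), i),
                    vapply(tr, `[`, character(1), i))

  # missing replicate names the slot
  broken <- samples[!(samples$condition == "ZT10" & samples$replicate == 3), ]
  expect_error(build_trials(broken), "ZT10")
})

test_that("consensus_rhythm flags planted signals and respects the gate", {
  samples <- circadian_samples(make_sample_sheet(
    sim_config(seed = 2, library_sizes = rep(1700000L, 55))))
  t_h <- condition_hour(samples$condition)
  # noiseless planted cosine, relative amplitude 0.8 -> consensus
  q <- 100 * (1 + 0.8 * cos(2 * pi * (t_h - 10) / 24))
  mat <- matrix(rep(q, each = 2), 2, dimnames = list(c("a", "b"),
                                                     samples$sample_id))
  r <- consensus_rhythm(mat, samples, 24)
  expect_true(all(r$consensus))
  expect_true(all(r[, pmax(trial_p1, trial_p2, trial_p3, trial_p4,
                           trial_p5) < 0.05]))
  # JTK contributes a 4 h-grid phase, so the 3-detector circular mean can
  # sit up to ~4/3 h off even on noiseless data
  expect_lt(max(circ_err(r$mean_phase_h, 10)), 1.5)

  # consensus is exactly "max trial p < 0.05"
  expect_equal(r$consensus,
               apply(as.matrix(r[, paste0("trial_p", 1:5), with = FALSE]) <
                       0.05, 1, all))

  # all-zero PAC included with p = 1
  mat0 <- rbind(mat, zero = 0)
  r0 <- consensus_rhythm(mat0, samples, 24)
  expect_equal(r0[pac_id == "zero", mean_p], 1)
  expect_false(r0[pac_id == "zero", consensus])

  # pure 12 h signal is null at period 24 and detected at period 12
  q12 <- 100 * (1 + 0.8 * cos(2 * pi * (t_h - 3) / 12))
  m12 <- matrix(rep(q12, each = 1), 1, dimnames = list("u", samples$sample_id))
  expect_false(consensus_rhythm(m12, samples, 24)$consensus)
  expect_true(consensus_rhythm(m12, samples, 12)$consensus)

  # result order follows input order (relabeling invariance)
  rswap <- consensus_rhythm(mat[c(2, 1), ], samples, 24)
  expect_equal(rswap$pac_id, c("b", "a"))
})

test_that("phase_bin assigns circular 5 h windows with dual membership", {
  res <- data.table::data.table(
    pac_id = c("a", "b", "c"), mean_phase_h = c(4.0, 23.9, 12.0))
  bins <- phase_bin(res)
  expect_true("a" %in% bins$ZT6)     # [3.5, 8.5]
  expect_true("a" %in% bins$ZT2)     # [23.5, 4.5] wraps
  expect_true("b" %in% bins$ZT22)    # [19.5, 0.5] wraps
  expect_true("b" %in% bins$ZT2)     # [23.5, 4.5] also wraps onto 23.9
  expect_false("b" %in% bins$ZT18)   # [15.5, 20.5] does not
  expect_setequal(names(bins)[vapply(bins, function(x) "c" %in% x,
                                     logical(1))], c("ZT10", "ZT14"))
})
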