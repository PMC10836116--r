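# Package-level cache for permutation matrices and JTK null distributions.
.apa_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an (n! x n) matrix. n <= 10 enforced upstream.
all_permutations <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.apa_cache[[key]])) return(.apa_cache[[key]])
  pm <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    old <- pm
    pm <- matrix(0L, nrow(old) * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * nrow(old) + seq_len(nrow(old))
      pm[rows, pos] <- k
      pm[rows, setdiff(seq_len(k), pos)] <- old
    }
  }
  .apa_cache[[key]] <- pm
  pm
}

pair_index <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ij[, "row"], j = ij[, "col"])
}

# Tie signature of a vector: sorted multiplicities, e.g. "1,1,2,2".
tie_signature <- function(x) paste(sort(table(x)), collapse = ",")

#' Exact null distribution of Kendall's tau against a fixed reference
#'
#' Enumerates all n! orderings of the observed values (conditional on their
#' tie pattern) and tabulates the tau-b statistic against the reference
#' vector. Used for JTK's exact per-lag p-values; exported so the
#' enumeration can be checked against independent oracles.
#'
#' @param values numeric vector (its tie pattern conditions the null).
#' @param reference numeric reference vector, same length.
#' @return data.table with columns \code{tau} and \code{prob}
#'   (probabilities sum to 1).
#' @export
jtk_null_distribution <- function(values, reference) {
  n <- length(values)
  stopifnot(length(reference) == n, n >= 2, n <= 10)
  nd <- jtk_null_cached(values, reference)
  data.table::data.table(tau = nd$tau, prob = nd$prob)
}

# Internal cached form. Returns list(tau, prob, abs_s, tail) where tail[k] =
# P(|S| >= abs_s[k]) for the sorted unique |S| values.
jtk_null_cached <- function(values, reference) {
  n <- length(values)
  key <- paste0("null|", n, "|", tie_signature(values), "|",
                paste(rank(reference, ties.method = "min"), collapse = "."))
  if (!is.null(.apa_cache[[key]])) return(.apa_cache[[key]])
  rep_y <- sort(values)             # representative with the same tie pattern
  pm <- all_permutations(n)
  pr <- pair_index(n)
  sr <- sign(reference[pr$i] - reference[pr$j])
  Y <- matrix(rep_y[pm], nrow(pm), n)
  SY <- sign(Y[, pr$i, drop = FALSE] - Y[, pr$j, drop = FALSE])
  S <- as.vector(SY %*% sr)
  n0 <- n * (n - 1) / 2
  n1 <- sum(sign(outer(rep_y, rep_y, `-`))[upper.tri(diag(n))] == 0)
  n2 <- sum(sr == 0)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom > 0) S / denom else rep(0, length(S))
  tb <- table(S)
  svals <- as.numeric(names(tb))
  probs <- as.numeric(tb) / length(S)
  o <- order(abs(svals))
  abs_s <- abs(svals)[o]
  # tail over |S|: collapse duplicate |S|
  agg <- tapply(probs[o], abs_s, sum)
  uabs <- as.numeric(names(agg))
  tail_p <- rev(cumsum(rev(as.numeric(agg))))
  out <- list(tau = if (denom > 0) svals / denom else svals * 0,
              prob = probs, denom = denom, abs_s = uabs, tail = tail_p)
  .apa_cache[[key]] <- out
  out
}

# ---------------------------------------------------------------------------
# Matrix-level detectors. Y is (series x timepoints); times in hours.
# Single implementation used by both the per-series API and consensus_rhythm.

cosinor_mat <- function(Y, times, period_h) {
  n <- length(times)
  if (n < 4) stop("cosinor fit needs >= 4 timepoints")
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * times), sin(w * times))
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi                     # (m x 3)
  fit <- B %*% t(X)
  res <- Y - fit
  rss <- rowSums(res^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  amp <- sqrt(B[, 2]^2 + B[, 3]^2)
  phase <- (atan2(B[, 3], B[, 2]) / w) %% period_h
  df2 <- n - 3
  Fstat <- ifelse(tss <= 0, 0,
                  ((tss - rss) / 2) / pmax(rss / df2, .Machine$double.xmin))
  p <- ifelse(tss <= 0, 1, pf(Fstat, 2, df2, lower.tail = FALSE))
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  amp[tss <= 0] <- 0
  phase[tss <= 0] <- 0
  list(p = p, phase_h = phase, amplitude = amp, statistic = Fstat,
       mesor = B[, 1])
}

ls_mat <- function(Y, times, period_h, null = c("exact", "asymptotic")) {
  null <- match.arg(null)
  n <- length(times)
  w <- 2 * pi / period_h
  tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
  ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
  cc <- sum(ct^2); ss <- sum(st^2)
  Yc <- Y - rowMeans(Y)
  s2 <- rowSums(Yc^2) / (n - 1)
  num_c <- as.vector(Yc %*% ct)
  num_s <- as.vector(Yc %*% st)
  P <- rep(0, nrow(Y))
  nz <- s2 > 0
  termc <- if (cc > 1e-12) num_c^2 / cc else 0
  terms <- if (ss > 1e-12) num_s^2 / ss else 0
  P[nz] <- ((termc + terms) / (2 * s2))[nz]
  p <- if (null == "asymptotic") exp(-P)
       else (pmax(1 - 2 * P / (n - 1), 0))^((n - 3) / 2)
  p <- pmax(p, .Machine$double.xmin)
  a <- if (cc > 1e-12) num_c / cc else rep(0, nrow(Y))
  b <- if (ss > 1e-12) num_s / ss else rep(0, nrow(Y))
  amp <- sqrt(a^2 + b^2)
  phase <- ((atan2(b, a) / w) + tau) %% period_h
  phase[!nz] <- 0; amp[!nz] <- 0
  list(p = p, phase_h = phase, amplitude = amp, statistic = P)
}

jtk_mat <- function(Y, times, period_h, phase_grid_h = 4) {
  n <- length(times)
  m <- nrow(Y)
  lags <- seq(0, period_h - phase_grid_h, by = phase_grid_h)
  pr <- pair_index(n)
  SY <- sign(Y[, pr$i, drop = FALSE] - Y[, pr$j, drop = FALSE])
  n0 <- n * (n - 1) / 2
  n1 <- rowSums(SY == 0)
  all_tied <- n1 == n0
  sig_y <- apply(Y, 1L, tie_signature)
  best_tau <- rep(0, m); best_p <- rep(1, m); best_lag <- rep(0, m)
  for (lag in lags) {
    ref <- cos(2 * pi * (times - lag) / period_h)
    sr <- sign(ref[pr$i] - ref[pr$j])
    n2 <- sum(sr == 0)
    S <- as.vector(SY %*% sr)
    denom <- sqrt((n0 - n1) * (n0 - n2))
    tau <- ifelse(denom > 0, S / denom, 0)
    p_lag <- rep(1, m)
    for (sg in unique(sig_y[!all_tied])) {
      rows <- which(sig_y == sg & !all_tied)
      nd <- jtk_null_cached(Y[rows[1], ], ref)
      # tail prob of |S| >= |S_obs|
      idx <- findInterval(abs(S[rows]) - 1e-9, nd$abs_s) + 1L
      p_lag[rows] <- ifelse(idx > length(nd$tail), 0, nd$tail[pmax(idx, 1L)])
      # |S|=0 sits at idx 1 -> tail prob 1
    }
    upd <- abs(tau) > abs(best_tau) + 1e-12      # strict: ties keep earliest lag
    best_tau[upd] <- tau[upd]; best_p[upd] <- p_lag[upd]
    best_lag[upd] <- lag
  }
  p <- pmin(best_p * length(lags), 1)
  p <- pmax(p, .Machine$double.xmin)
  p[all_tied] <- 1
  phase <- ifelse(best_tau >= 0, best_lag,
                  (best_lag + period_h / 2) %% period_h)
  phase[all_tied] <- 0
  list(p = p, phase_h = phase, statistic = best_tau, lag_h = best_lag)
}

# ---------------------------------------------------------------------------

as_detector_result <- function(method, x, i = 1L) {
  list(method = method, p = x$p[i], phase_h = x$phase_h[i],
       amplitude = if (!is.null(x$amplitude)) x$amplitude[i] else NA_real_,
       statistic = x$statistic[i])
}

#' Cosinor (harmonic regression) rhythm detector
#'
#' Least-squares fit of y = M + A cos(2 pi (t - phi) / period); significance
#' by the F test of the two harmonic coefficients against the constant model
#' with (2, n - 3) degrees of freedom. The acrophase phi is the argmax of
#' the fitted curve in [0, period). Constant series return A = 0, p = 1.
#'
#' @param values numeric series (one replicate per timepoint).
#' @param times timepoints in hours, strictly increasing, length >= 4.
#' @param period_h target period in hours (24 or 12 here).
#' @return DetectorResult: list(method, p, phase_h, amplitude, statistic).
#' @export
cosinor_fit <- function(values, times, period_h) {
  check_series(values, times)
  r <- cosinor_mat(matrix(values, 1L), times, period_h)
  out <- as_detector_result("COSINOR", r)
  out$mesor <- r$mesor[1]
  out
}

#' Lomb-Scargle rhythm detector at a single target frequency
#'
#' Classical normalized periodogram power P at the target frequency (with
#' the standard per-frequency time offset tau), normalized by the sample
#' variance (n - 1 denominator). A noiseless sinusoid at the target period
#' gives the maximal power P = (n - 1) / 2; zero-variance series return
#' power 0, p = 1. The power is invariant to adding a constant and to
#' positive rescaling.
#'
#' Two null models are offered. \code{"asymptotic"} is the classical
#' single-frequency tail p = exp(-P), which assumes a known noise variance;
#' at the 6-point design used here it is visibly anti-conservative because
#' the variance is estimated from the same 6 values. The default
#' \code{"exact"} uses the finite-sample null of the sample-variance-
#' normalized periodogram, p = (1 - 2P/(n-1))^((n-3)/2), which is calibrated
#' at any n (Schwarzenberg-Czerny's Beta form).
#'
#' @inheritParams cosinor_fit
#' @param null "exact" (default) or "asymptotic"; see Details.
#' @return DetectorResult; \code{statistic} is the periodogram power.
#' @export
lomb_scargle <- function(values, times, period_h,
                         null = c("exact", "asymptotic")) {
  check_series(values, times)
  as_detector_result("LS", ls_mat(matrix(values, 1L), times, period_h,
                                  null = null))
}

#' JTK-style rhythm detector with exact permutation null
#'
#' Computes Kendall's tau-b between the series and a cosine reference at
#' each candidate phase lag (default grid = the 4 h sampling resolution),
#' selects the lag with the largest |tau|, and takes the per-lag p-value
#' from the exact distribution of tau over all n! orderings of the observed
#' values (conditional on their tie pattern; ties in the reference ranks are
#' handled by tau-b). The reported p is Bonferroni-adjusted for the number
#' of lags and capped at 1. All-tied series return p = 1.
#'
#' @inheritParams cosinor_fit
#' @param phase_grid_h spacing of candidate phase lags in hours (default 4).
#' @return DetectorResult; \code{statistic} is the best tau,
#'   \code{phase_h} the corresponding acrophase (lag + period/2 when tau is
#'   negative).
#' @export
jtk_cycle <- function(values, times, period_h, phase_grid_h = 4) {
  check_series(values, times)
  if (length(values) > 10)
    stop("exact JTK null is enumerated only for n <= 10")
  r <- jtk_mat(matrix(values, 1L), times, period_h, phase_grid_h)
  out <- list(method = "JTK", p = r$p[1], phase_h = r$phase_h[1],
              amplitude = NA_real_, statistic = r$statistic[1])
  out
}

check_series <- function(values, times) {
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (length(times) < 4) stop("need >= 4 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}

#' Integrate detector results into one meta statistic
#'
#' Combined p-value by Fisher's method (X^2 = -2 sum log p_i on 2k degrees
#' of freedom; p_i clamped to the smallest positive double before the log),
#' phase by the circular mean of detector phases on the period circle, and
#' amplitude from the cosinor detector when present (otherwise the mean of
#' the available amplitudes).
#'
#' @param results list of DetectorResult objects (>= 1).
#' @param period_h period in hours for the circular phase mean.
#' @return list(meta_p, meta_phase_h, meta_amplitude).
#' @export
integrate_meta <- function(results, period_h) {
  stopifnot(length(results) >= 1)
  ps <- vapply(results, `[[`, numeric(1), "p")
  ps <- pmax(ps, .Machine$double.xmin)
  x2 <- -2 * sum(log(ps))
  meta_p <- pchisq(x2, df = 2 * length(ps), lower.tail = FALSE)
  phases <- vapply(results, `[[`, numeric(1), "phase_h")
  amps <- vapply(results, `[[`, numeric(1), "amplitude")
  meth <- vapply(results, `[[`, character(1), "method")
  amp <- if (any(meth == "COSINOR")) amps[match("COSINOR", meth)]
         else mean(amps, na.rm = TRUE)
  list(meta_p = max(meta_p, .Machine$double.xmin),
       meta_phase_h = circular_mean_phase(phases, period_h),
       meta_amplitude = amp)
}

#' Build the 5 replicate-slotted trials
#'
#' Trial j assigns exactly one replicate to each timepoint slot. The default
#' deterministic \code{rotation} scheme gives slot i replicate
#' \code{((i + j - 2) mod 5) + 1} — a Latin square, so across the 5 trials
#' every replicate appears exactly once in every slot. The
#' \code{seeded_random} scheme draws an independent permutation of the 5
#' replicates for each slot from \code{seed}.
#'
#' @param samples sample sheet restricted to a complete circadian design
#'   (each timepoint condition with the same replicate set).
#' @param scheme "rotation" (default) or "seeded_random".
#' @param seed RNG seed for the seeded_random scheme.
#' @param conditions timepoint condition labels in time order.
#' @return list of 5 character vectors of sample ids, each ordered by
#'   timepoint.
#' @export
build_trials <- function(samples, scheme = c("rotation", "seeded_random"),
                         seed = 1L,
                         conditions = c("ZT2", "ZT6", "ZT10", "ZT14",
                                        "ZT18", "ZT22")) {
  scheme <- match.arg(scheme)
  n_rep <- 5L
  idx <- lapply(conditions, function(cond) {
    rows <- samples[samples$condition == cond, ]
    ids <- rows$sample_id[match(seq_len(n_rep), rows$replicate)]
    if (anyNA(ids))
      stop("missing replicate in slot ", cond, ": need replicates 1..5")
    ids
  })
  if (scheme == "rotation") {
    lapply(seq_len(n_rep), function(j)
      vapply(seq_along(conditions), function(i)
        idx[[i]][((i + j - 2L) %% n_rep) + 1L], character(1)))
  } else {
    set.seed(derive_seed(seed, "trials"))
    perm <- lapply(seq_along(conditions), function(i) sample.int(n_rep))
    lapply(seq_len(n_rep), function(j)
      vapply(seq_along(conditions), function(i)
        idx[[i]][perm[[i]][j]], character(1)))
  }
}

#' Consensus rhythm detection across 5 replicate-slotted trials
#'
#' For every PAC and every trial, runs the three detectors (Lomb-Scargle,
#' JTK, cosinor) on the trial's 6-point series and integrates them by
#' Fisher's method; then averages across trials: \code{mean_p} is the
#' arithmetic mean of the 5 trial meta-p values, \code{mean_fdr} the mean of
#' the within-trial Benjamini-Hochberg adjusted meta-p, \code{mean_phase_h}
#' the circular mean of trial phases, and \code{consensus} is TRUE iff all 5
#' trial meta-p are < \code{alpha}. All-zero (constant) series get trial
#' p = 1 and are kept in the FDR denominators.
#'
#' @param mat count matrix (PAC x sample); raw or normalized counts
#'   depending on the caller's choice.
#' @param samples sample sheet covering the circadian design.
#' @param period_h target period (24 or 12).
#' @param scheme,seed trial construction, see [build_trials()].
#' @param alpha per-trial significance gate for the consensus flag
#'   (default 0.05).
#' @param phase_grid_h JTK phase grid (default 4 h, the sampling interval).
#' @return data.table: pac_id, period_h, trial_p1..trial_p5, mean_p,
#'   mean_fdr, mean_phase_h, mean_amplitude, consensus.
#' @export
consensus_rhythm <- function(mat, samples, period_h,
                             scheme = "rotation", seed = 1L, alpha = 0.05,
                             phase_grid_h = 4) {
  circ <- circadian_samples(data.table::as.data.table(samples))
  trials <- build_trials(circ, scheme = scheme, seed = seed)
  conditions <- c("ZT2", "ZT6", "ZT10", "ZT14", "ZT18", "ZT22")
  times <- condition_hour(conditions)
  m <- nrow(mat)
  tp <- matrix(NA_real_, m, 5L)
  tfdr <- matrix(NA_real_, m, 5L)
  tphase <- matrix(NA_real_, m, 5L)
  tamp <- matrix(NA_real_, m, 5L)
  for (j in seq_along(trials)) {
    Y <- mat[, trials[[j]], drop = FALSE]
    co <- cosinor_mat(Y, times, period_h)
    ls <- ls_mat(Y, times, period_h)
    jt <- jtk_mat(Y, times, period_h, phase_grid_h)
    ps <- cbind(pmax(ls$p, .Machine$double.xmin),
                pmax(jt$p, .Machine$double.xmin),
                pmax(co$p, .Machine$double.xmin))
    x2 <- -2 * rowSums(log(ps))
    meta_p <- pmax(pchisq(x2, df = 6, lower.tail = FALSE),
                   .Machine$double.xmin)
    # circular mean of the three detector phases, per PAC
    th <- 2 * pi / period_h
    sin_m <- (sin(ls$phase_h * th) + sin(jt$phase_h * th) +
                sin(co$phase_h * th)) / 3
    cos_m <- (cos(ls$phase_h * th) + cos(jt$phase_h * th) +
                cos(co$phase_h * th)) / 3
    tp[, j] <- meta_p
    tfdr[, j] <- p.adjust(meta_p, method = "BH")
    tphase[, j] <- (atan2(sin_m, cos_m) / th) %% period_h
    tamp[, j] <- co$amplitude
  }
  th <- 2 * pi / period_h
  mean_phase <- (atan2(rowMeans(sin(tphase * th)),
                       rowMeans(cos(tphase * th))) / th) %% period_h
  out <- data.table::data.table(
    pac_id = rownames(mat) %||% sprintf("row%d", seq_len(m)),
    period_h = period_h,
    trial_p1 = tp[, 1], trial_p2 = tp[, 2], trial_p3 = tp[, 3],
    trial_p4 = tp[, 4], trial_p5 = tp[, 5],
    mean_p = rowMeans(tp), mean_fdr = rowMeans(tfdr),
    mean_phase_h = mean_phase, mean_amplitude = rowMeans(tamp),
    consensus = apply(tp < alpha, 1L, all))
  out[]
}

#' Bin rhythmic PACs into sliding circular phase windows
#'
#' Each PAC joins every window \code{[center - halfwidth, center +
#' halfwidth]} (circular, boundaries inclusive) that contains its mean
#' phase. With the default 5 h windows centered on the collection
#' timepoints, adjacent windows overlap by 1 h, so dual membership occurs.
#'
#' @param results output of [consensus_rhythm()] (or any table with pac_id
#'   and mean_phase_h).
#' @param centers_h window centers in hours (default the ZT collection
#'   times).
#' @param halfwidth_h half window width in hours (default 2.5).
#' @param period_h circle period (default 24).
#' @return named list: center -> character vector of pac_ids.
#' @export
phase_bin <- function(results, centers_h = c(2, 6, 10, 14, 18, 22),
                      halfwidth_h = 2.5, period_h = 24) {
  res <- data.table::as.data.table(results)
  out <- lapply(centers_h, function(ctr) {
    d <- abs(circular_diff_h(res$mean_phase_h, ctr, period_h))
    res$pac_id[d <= halfwidth_h]
  })
  names(out) <- paste0("ZT", centers_h)
  out
}
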