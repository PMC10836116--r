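#' Remove the first principal component from a log-scale matrix
#'
#' Rows are centered, the rank-1 component of the first singular triplet of
#' the centered matrix is subtracted, and the row means are restored. Used
#' to strip dominant systematic variation before dispersion estimation; the
#' caller is expected to pass log2(normalized count + 1) values.
#'
#' When \code{groups} is supplied the nuisance direction is estimated on the
#' within-group-centered residual matrix instead. Its right singular vector
#' is then orthogonal to the group-indicator space, so subtracting the data's
#' projection onto it can never remove the tested contrast (group means are
#' preserved exactly) — the safe form used by [run_contrasts()], where a
#' design-blind PC1 would absorb a strong treatment effect.
#'
#' @param logmat numeric matrix (features x samples), >= 3 samples.
#' @param groups optional factor of sample groups; see Details.
#' @return matrix of the same shape with PC1 removed and row means intact.
#' @export
remove_pc1 <- function(logmat, groups = NULL) {
  if (ncol(logmat) < 3L) stop("remove_pc1 needs at least 3 samples")
  if (is.null(groups)) {
    rm_ <- rowMeans(logmat)
    xc <- logmat - rm_
    sv <- svd(xc, nu = 1L, nv = 1L)
    out <- xc - sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
    return(out + rm_)
  }
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(logmat))
  res <- logmat
  for (g in levels(groups)) {
    ix <- which(groups == g)
    res[, ix] <- logmat[, ix, drop = FALSE] -
      rowMeans(logmat[, ix, drop = FALSE])
  }
  sv <- svd(res, nu = 0L, nv = 1L)
  v1 <- sv$v[, 1]
  logmat - tcrossprod(logmat %*% v1, v1)
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per-sample median of count ratios to the row-wise geometric
#' mean, over features with all-nonzero counts. When fewer than
#' \code{min_nonzero} such features exist, falls back to library totals
#' (rescaled to geometric mean 1).
#'
#' @param counts count matrix (features x samples).
#' @param min_nonzero minimum all-nonzero features for median-of-ratios
#'   (default 50).
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts, min_nonzero = 50L) {
  allnz <- rowSums(counts == 0) == 0
  if (sum(allnz) >= min_nonzero) {
    lg <- log(counts[allnz, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2L, median)
  } else {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total counts")
    sf <- tot / exp(mean(log(tot)))
  }
  sf
}

#' Per-feature NB dispersion by method of moments with trend shrinkage
#'
#' Within each group, alpha is estimated as
#' \code{(s^2 - m * mean(1/sf)) / m^2} on the size-factor-normalized scale,
#' pooled across groups by residual degrees of freedom and floored at 0.
#' Raw estimates are then shrunk toward a fitted mean-dispersion trend
#' \code{alpha(mu) = a0 + a1/mu} with weight \code{w = d / (d + d0)} on the
#' raw estimate (d = residual df, prior df d0 = 8), and floored at 1e-8.
#' Zero-mean features get NA (the Wald test reports p = 1 for them).
#'
#' @param counts count matrix (features x samples).
#' @param groups factor of group labels (>= 2 replicates per group).
#' @param sf size factors (default from [size_factors()]).
#' @param prior_df prior degrees of freedom of the trend (default 8).
#' @return numeric vector of dispersions (NA for zero-mean features).
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                prior_df = 8) {
  groups <- as.factor(groups)
  norm <- sweep(counts, 2L, sf, `/`)
  mu_all <- rowMeans(norm)
  acc <- rep(0, nrow(counts)); wsum <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    if (length(ix) < 2L) stop("group ", g, " has < 2 replicates")
    m <- rowMeans(norm[, ix, drop = FALSE])
    v <- apply(norm[, ix, drop = FALSE], 1L, var)
    a_g <- ifelse(m > 0, (v - m * mean(1 / sf[ix])) / m^2, NA_real_)
    w_g <- length(ix) - 1L
    acc <- acc + ifelse(is.na(a_g), 0, a_g) * w_g
    wsum <- wsum + w_g
  }
  raw <- pmax(acc / wsum, 0)
  raw[mu_all == 0] <- NA_real_
  ok <- !is.na(raw) & mu_all > 0
  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fit on positive raw values
  fit_ok <- ok & raw > 0
  trend <- rep(mean(raw[ok]), length(raw))
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(raw[fit_ok] ~ I(1 / mu_all[fit_ok])))
    co <- pmax(co, 0)
    trend <- co[1] + co[2] / pmax(mu_all, 1e-8)
  }
  d <- wsum
  w <- d / (d + prior_df)
  out <- w * raw + (1 - w) * trend
  pmax(out, 1e-8)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits the NB log-linear model \code{log mu = b0 + b1 * [treatment] +
#' log(size factor)} by iteratively reweighted least squares at fixed
#' dispersion alpha, and tests b1 = 0 with the Wald z statistic
#' (two-sided normal p). The fold change is reported in log2 units.
#' All-zero features return p = 1 and log2fc = 0; a group that is entirely
#' zero yields a large but finite estimate (|b1| capped at 30 on the
#' natural-log scale), to be tamed by [shrink_lfc()].
#'
#' @param y count vector (one feature).
#' @param treatment logical/0-1 vector: TRUE for treatment samples.
#' @param sf size factors (offsets).
#' @param alpha NB dispersion (variance = mu + alpha mu^2); NA gives p = 1.
#' @return list(log2fc_mle, se_log2, wald_z, p, converged).
#' @export
nb_wald <- function(y, treatment, sf = rep(1, length(y)), alpha) {
  x <- as.numeric(treatment)
  stopifnot(length(y) == length(x), length(sf) == length(y))
  if (is.na(alpha) || all(y == 0))
    return(list(log2fc_mle = 0, se_log2 = NA_real_, wald_z = 0, p = 1,
                converged = TRUE))
  X <- unname(cbind(1, x))
  off <- log(sf)
  mu0 <- mean(y / sf)
  beta <- c(log(max(mu0, 1e-8)), 0)
  conv <- FALSE
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    xtw <- crossprod(X, w * X)
    if (rcond(xtw) < 1e-14) break
    newb <- solve(xtw, crossprod(X, w * z))
    newb[2] <- pmax(pmin(newb[2], 30), -30)
    newb[1] <- pmax(pmin(newb[1], 50), -50)
    if (max(abs(newb - beta)) < 1e-10) {
      beta <- unname(drop(newb)); conv <- TRUE; break
    }
    beta <- unname(drop(newb))
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
  if (is.null(cov) || cov[2, 2] <= 0)
    return(list(log2fc_mle = beta[2] / log(2), se_log2 = NA_real_, wald_z = 0,
                p = 1, converged = FALSE))
  se <- sqrt(cov[2, 2])
  zstat <- beta[2] / se
  list(log2fc_mle = beta[2] / log(2), se_log2 = se / log(2), wald_z = zstat,
       p = max(2 * pnorm(abs(zstat), lower.tail = FALSE),
               .Machine$double.xmin),
       converged = conv)
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Posterior mode under a zero-centered Cauchy prior on the log2 fold
#' change, with a normal likelihood centered at the MLE with its standard
#' error. The prior scale is fit once by maximizing the marginal likelihood
#' of the observed MLEs (normal noise integrated by a 32-node
#' probability-integral quadrature). The shrunk estimate always lies
#' between 0 and the MLE, so the sign never flips.
#'
#' @param mle vector of MLE log2 fold changes.
#' @param se vector of their standard errors (NA entries are returned as 0).
#' @param scale optional fixed Cauchy scale; default fits it empirically.
#' @return list(shrunk = vector, scale = fitted prior scale).
#' @export
shrink_lfc <- function(mle, se, scale = NULL) {
  ok <- !is.na(se) & se > 0 & is.finite(mle)
  if (is.null(scale)) {
    nodes <- qnorm((seq_len(32L) - 0.5) / 32L)
    mloglik <- function(s) {
      fi <- vapply(which(ok), function(i)
        mean(dcauchy(mle[i] - se[i] * nodes, 0, s)), numeric(1))
      -sum(log(pmax(fi, 1e-300)))
    }
    scale <- if (sum(ok) >= 5)
      optimize(mloglik, c(1e-3, 20))$minimum else 1
  }
  shrunk <- numeric(length(mle))
  for (i in which(ok)) {
    if (mle[i] == 0) next
    if (se[i] < 1e-8) { shrunk[i] <- mle[i]; next }
    obj <- function(b) (b - mle[i])^2 / (2 * se[i]^2) -
      dcauchy(b, 0, scale, log = TRUE)
    shrunk[i] <- optimize(obj, sort(c(0, mle[i])))$minimum
  }
  list(shrunk = shrunk, scale = scale)
}

#' Local false discovery rate from an empirical null
#'
#' Fits the empirical null by central matching — location = median(z),
#' scale = MAD(z) — estimates pi0 from the central +/- 1 scale region, and
#' the mixture density f by kernel density estimation;
#' \code{lfdr(z) = min(1, pi0 * f0(z) / f(z))}. With fewer than
#' \code{min_n} values the fit is unstable: NA is returned with a warning
#' (callers fall back to BH-adjusted p-values).
#'
#' @param z vector of z statistics.
#' @param min_n minimum number of values (default 200).
#' @return numeric vector of lfdr values in [0, 1] (or NAs on fallback).
#' @export
local_fdr <- function(z, min_n = 200L) {
  z <- as.numeric(z)
  if (sum(is.finite(z)) < min_n) {
    warning("fewer than ", min_n, " finite z-values: local FDR not ",
            "estimated, use BH-adjusted p-values")
    return(rep(NA_real_, length(z)))
  }
  zf <- z[is.finite(z)]
  delta <- median(zf)
  s0 <- mad(zf, center = delta)
  if (s0 <= 0) s0 <- sd(zf)
  central <- mean(abs(zf - delta) <= s0)
  pi0 <- min(1, central / (2 * pnorm(1) - 1))
  dens <- density(zf, n = 1024)
  fz <- approx(dens$x, dens$y, xout = z, rule = 2)$y
  pmin(1, pi0 * dnorm(z, delta, s0) / pmax(fz, 1e-300))
}

#' The four sleep-deprivation recovery contrasts
#' @return list of c(treatment, control) pairs.
#' @export
sd_contrasts <- function() {
  list(c("R0", "ZT6"), c("R2", "ZT8"), c("R4", "ZT10"), c("R8", "ZT14"))
}

#' Differential PAC expression across sleep-deprivation recovery contrasts
#'
#' Per contrast (treatment vs time-matched control, 5 replicates each):
#' median-of-ratios size-factor normalization, log2(x+1) transform, PC1
#' removal ([remove_pc1()]), back-transform (2^x - 1, floored at 0),
#' method-of-moments dispersion with trend shrinkage, NB Wald test, Cauchy
#' shrinkage of log2 fold changes, Benjamini-Hochberg adjustment, and local
#' FDR on the Wald z values. A feature is flagged significant when
#' p < \code{p_gate} and |shrunk log2FC| > \code{lfc_gate}; the
#' \code{multi_apa} column additionally requires membership in
#' \code{multi_apa_genes} (when annotations are supplied).
#'
#' @param counts raw count matrix (PAC x sample).
#' @param samples sample sheet.
#' @param contrasts list of c(treatment, control) pairs (default
#'   [sd_contrasts()]).
#' @param annotations optional [annotate_pacs()] table for the multi-APA
#'   gate.
#' @param p_gate,lfc_gate significance gates (defaults 0.01 and 0.5).
#' @param pc1_remove logical; strip PC1 before dispersion/Wald (default
#'   TRUE).
#' @return data.table: pac_id, contrast, base_mean, log2fc_mle,
#'   log2fc_shrunk, se, wald_z, p, p_bh, lfdr, significant, multi_apa.
#' @export
run_contrasts <- function(counts, samples, contrasts = sd_contrasts(),
                          annotations = NULL, p_gate = 0.01, lfc_gate = 0.5,
                          pc1_remove = TRUE) {
  samples <- data.table::as.data.table(samples)
  multi_genes <- if (!is.null(annotations))
    multi_apa_gene_set(annotations) else NULL
  out <- lapply(contrasts, function(ct) {
    trt <- ct[1]; ctl <- ct[2]
    for (g in c(trt, ctl))
      if (!any(samples$condition == g))
        stop("missing condition group: ", g)
    cols <- samples[samples$condition %in% c(trt, ctl), sample_id]
    sub <- counts[, cols, drop = FALSE]
    grp <- samples$condition[match(cols, samples$sample_id)] == trt
    sf <- size_factors(sub)
    norm <- sweep(sub, 2L, sf, `/`)
    mat <- if (pc1_remove) {
      lg <- log2(norm + 1)
      lg1 <- remove_pc1(lg, groups = factor(grp))
      # the removed nuisance direction costs one residual degree of freedom:
      # rescale within-group residuals by sqrt(q/(q-1)) so downstream
      # dispersion estimates stay calibrated
      q <- ncol(lg1) - 2L
      for (gv in c(TRUE, FALSE)) {
        ix <- which(grp == gv)
        gmean <- rowMeans(lg1[, ix, drop = FALSE])
        lg1[, ix] <- gmean + (lg1[, ix, drop = FALSE] - gmean) *
          sqrt(q / (q - 1L))
      }
      pmax(2^lg1 - 1, 0)
    } else norm
    alpha <- estimate_dispersion(mat, factor(grp), sf = rep(1, ncol(mat)))
    wald <- lapply(seq_len(nrow(mat)), function(i)
      nb_wald(mat[i, ], grp, sf = rep(1, ncol(mat)), alpha = alpha[i]))
    res <- data.table::data.table(
      pac_id = rownames(counts) %||% sprintf("row%d", seq_len(nrow(counts))),
      contrast = paste0(trt, "_vs_", ctl),
      base_mean = rowMeans(norm),
      log2fc_mle = vapply(wald, `[[`, numeric(1), "log2fc_mle"),
      se = vapply(wald, `[[`, numeric(1), "se_log2"),
      wald_z = vapply(wald, `[[`, numeric(1), "wald_z"),
      p = vapply(wald, `[[`, numeric(1), "p"))
    res[, log2fc_shrunk := shrink_lfc(log2fc_mle, se)$shrunk]
    res[, p_bh := p.adjust(p, method = "BH")]
    res[, lfdr := suppressWarnings(local_fdr(wald_z))]
    res[, significant := p < p_gate & abs(log2fc_shrunk) > lfc_gate]
    res[, multi_apa := if (is.null(multi_genes)) NA else
      significant & pac_id %in%
        annotations$pac_id[annotations$gene_id %in% multi_genes]]
    res
  })
  data.table::rbindlist(out)
}
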