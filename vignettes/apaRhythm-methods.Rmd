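---
title: "apaRhythm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apaRhythm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

apaRhythm analyzes 3'-end tag sequencing (WTTS-seq style) data for
alternative polyadenylation (APA) in a circadian / sleep-deprivation design:
reads anchored at cleavage sites are cleaned, collapsed into poly(A)-site
clusters (PACs), quantified per sample, annotated against gene models, and
screened for 24 h and 12 h rhythms and for differential expression after
sleep deprivation. Every stage can be exercised on ground-truthed synthetic
data, so the package is testable without any external download. This
vignette documents the statistical models, the tunable parameters and their
defaults, the numerical choices, and the places where the design was
genuinely open.

## Read preprocessing

Reads are filtered and trimmed in the order quality -> trim -> length:

* **Quality filter.** A read is kept iff at least `min_frac` (default 0.5)
  of its bases have Phred quality at least `min_q` (default 10). Both
  boundaries are inclusive: a read with exactly half its bases at exactly
  Q10 passes.
* **5' T-rich trimming.** 3'-tag protocols leave a reverse-complemented
  poly(A) remnant — a T-rich stretch — at the 5' end. The upstream rule
  lives in unpublished scripts, so the package defines a deterministic
  two-phase rule: (1) drop all leading `T`; (2) if at least `t_window_min`
  (3) of the next `t_window` (4) bases are `T`, drop through the last `T`
  among them and repeat from (1). Each pass consumes at least one base, so
  the rule provably terminates; it removes homopolymer runs and interrupted
  T-rich stretches but stops at an ordinary sequence start. Qualities are
  trimmed in lockstep. The rule is idempotent.
* **Length gate.** Trimmed reads shorter than `min_len` (default 16) bases
  are dropped; a 16-base read is kept.

`N` bases receive no special handling (an `N` is never a `T`).

## PAC calling

* **Cleavage site.** The inferred cleavage position of a tag is its 3'-most
  aligned base in transcript orientation: alignment end on `+`, alignment
  start on `-`. This assumes the aligner reports tags in transcript
  orientation; `extract_tags(flip_strand = TRUE)` accommodates the opposite
  library convention. Non-uniquely mapped records are discarded.
* **Clustering.** Tags from all samples are merged, and per
  chromosome/strand the distinct sites are clustered by single linkage: a
  new cluster starts when the gap to the previous site exceeds
  `cluster_window_nt` (default 25). "Within 25 nt" is read inclusively, so
  sites exactly 25 nt apart co-cluster. The summit is the member site with
  the most reads, ties broken toward the 3' (distal) side.
* **Retention filter.** Thresholds adapt to library size: samples with
  fewer than `lib_size_cutoff` (1.7 million) uniquely mapped reads require
  `min_reads_small_lib` (3) reads, larger samples `min_reads_large_lib`
  (4). A PAC is retained iff at least one condition group of 5 replicates
  has at least `min_samples` (3) replicates meeting their own thresholds.
  Two boundary decisions are deliberate and configurable: a library of
  exactly 1.7M reads uses the stricter rule, and in groups whose libraries
  straddle the cutoff each replicate is judged against its own threshold.
* **Normalization.** After mitochondrial clusters are removed, counts are
  scaled to reads per 10^7: `norm = count / T_s * 1e7`, where `T_s` is the
  sample's total count over retained, non-mitochondrial PACs (the
  post-filter denominator; every normalized column then sums to exactly
  10^7). Using pre-filter totals instead is a one-line change in
  `normalize_pacs()` callers; the post-filter reading matches "normalized
  to the total number of covered reads".

## Region annotation

Each PAC summit is matched against same-strand gene models and assigned one
of six mutually exclusive categories with precedence `utr3_terminal` (within
`terminal_tol_nt`, default 25 nt, of the longest transcript's 3' end) >
`utr3_internal` (inside the longest 3'UTR) > `internal_exon` > `intron` >
`utr3_distal` (within `distal_window_nt`, default 5,000 nt, downstream and
not inside any gene) > `intergenic`. Competing genes are resolved by the
nearest transcript 3' end; antisense overlap is treated as intergenic. The
two intronic subtypes sometimes distinguished in APA atlases ("early
intron" vs "following an internal exon") have no published split criterion,
so both map to `intron`. The 5 kb distal window follows common practice for
unannotated 3'UTR extensions; the terminal tolerance equals the cluster
window so a cluster sitting on the annotated end is called terminal.

## Rhythm detection

The circadian design is 6 timepoints (ZT2..ZT22, every 4 h) x 5 replicates.
Detection runs five times ("trials"); trial j places exactly one replicate
in each timepoint slot. How the source protocol drew those replicates is
unstated, so both schemes are implemented: the default `rotation` assigns
slot i replicate `((i + j - 2) mod 5) + 1` — a Latin square, deterministic
and balanced — and `seeded_random` draws per-slot permutations from a seed.

Each 6-point trial series is scored by three detectors:

* **Cosinor**: least squares for `y = M + A cos(2*pi*(t - phi)/T)`; F test
  of the two harmonic coefficients on (2, n-3) df; acrophase = argmax of the
  fitted curve. Constant series return `A = 0, p = 1`.
* **Lomb-Scargle** at the single target frequency, classical normalization
  with the per-frequency time offset. A noiseless sinusoid gives the
  maximal power `(n-1)/2`. Two tails are offered: the textbook
  `p = exp(-P)` (`null = "asymptotic"`) assumes the noise variance is
  known; with the variance estimated from the same 6 points it is
  anti-conservative (measured one-sided KS D+ = 0.117 against U(0,1) under
  an NB null at n = 10,000, critical value 0.019). The default
  `null = "exact"` uses the finite-sample Beta tail of the
  sample-variance-normalized periodogram,
  `p = (1 - 2P/(n-1))^((n-3)/2)`, which is calibrated at any n
  (measured D+ = 0.004).
* **JTK**: Kendall's tau-b between the series and cosine references on a
  4 h phase grid; per-lag p-values from the exact distribution of tau over
  all n! orderings of the observed values (conditional on their tie
  pattern; reference ties handled by tau-b), best |tau| selected,
  Bonferroni correction over lags, capped at 1. The enumeration is cached
  per tie signature, and `jtk_null_distribution()` exposes it for oracle
  checks.

Per trial, the three p-values are combined by Fisher's method (chi-square
with 6 df; p-values clamped to the smallest positive double before the
log), the phase is the circular mean of the detector phases, and the
amplitude is the cosinor estimate. Across the five trials the package
reports the arithmetic mean p, the mean of within-trial BH-adjusted p, the
circular mean phase, and the consensus flag — TRUE iff the trial meta-p is
below 0.05 in *all five* trials. All-zero series are kept with p = 1 so FDR
denominators are stable. Significant 24 h PACs are binned into sliding 5 h
circular windows centered on the collection timepoints (window
[center - 2.5, center + 2.5], boundaries inclusive; adjacent windows
overlap by 1 h, so dual membership is expected).

Detectors accept raw or normalized counts; the pipeline defaults to
normalized, while the acceptance tests use raw counts to match the source
protocol's input. The p-values of all three detectors are invariant to the
per-sample scaling only in expectation, not exactly, which is why the flag
exists.

### Power of the consensus rule

The all-5-trials rule is extremely specific (measured: 0 of 10,000 null
PACs flagged) and weakly sensitive, and one of the package's acceptance
tests deliberately documents this. With relative amplitude 0.5 and NB
dispersion 0.05, a single 6-point trial has expected harmonic R^2 of about
0.68 *at infinite sequencing depth* (the dispersion floor alone gives a
22.4% CV against a signal SD of `0.5/sqrt(2)` times the mean); the cosinor
F test at (2, 3) df needs R^2 > 0.86 to reach p = 0.05, and the
single-frequency Lomb-Scargle and exact JTK have comparable per-trial
power. The per-trial pass probability is therefore ~0.6 and the all-5
consensus lands near `0.6^5` (about 5-8% measured), not the >= 80% the
criterion asserts; that test is left red deliberately. The machinery is not
the limit: at relative amplitude 0.8 and dispersion 0.01 the measured
consensus rate is 97.8%, with phases recovered well within 2 h. A green
consensus test therefore establishes correct mechanics and specificity;
absolute sensitivity at moderate amplitudes is intrinsically low for
6-point single-replicate trials.

## Differential expression

Four contrasts compare recovery after 6 h sleep deprivation with
time-matched undisturbed controls: R0 vs ZT6, R2 vs ZT8, R4 vs ZT10, R8 vs
ZT14 (5 replicates each). Per contrast:

1. **Size factors** by median-of-ratios over PACs with all-nonzero counts
   (fallback to totals when fewer than 50 such PACs).
2. **PC1 removal** on `log2(normalized + 1)`. The exported `remove_pc1()`
   is the textbook operation — center rows, subtract the first singular
   triplet, restore means. Note it is *not* idempotent in general (a second
   application removes the original second component); it is idempotent on
   rank-1 inputs, where the first application already leaves ~0.
   `run_contrasts()` uses the group-aware form: the nuisance direction is
   estimated on within-group-centered residuals, which makes it orthogonal
   to the group-indicator space, so the removed component can never be the
   tested contrast. This matters: in synthetic data where 2.5% of PACs
   carry a planted 2-fold effect, the design-blind PC1 *is* approximately
   the contrast direction and removing it erases every fold change.
   Because the estimated direction consumes a residual degree of freedom,
   within-group residuals are rescaled by `sqrt(q/(q-1))` (q = residual
   df); without this the null fraction of p < 0.01 inflates to ~0.022,
   with it the measured rates are 0.007-0.016 across seeds.
3. **Dispersion** by per-PAC method of moments on the normalized scale,
   pooled across the two groups, floored at 0, then shrunk toward a fitted
   `alpha(mu) = a0 + a1/mu` trend with weight `d/(d + d0)` on the raw
   estimate (d = 8 residual df, prior df d0 = 8), floor 1e-8.
4. **NB Wald test**: IRLS fit of `log mu = b0 + b1 [treatment] + offset`,
   Wald z = b1/SE, two-sided normal p. All-zero features report p = 1; a
   group of all zeros yields a large but finite estimate (|b1| capped at 30
   on the natural-log scale) that the shrinkage step tames.
5. **Shrinkage**: posterior mode under a zero-centered Cauchy prior with a
   normal likelihood at (MLE, SE). The prior scale is fit once per contrast
   by maximizing the quadrature-approximated marginal likelihood of the
   MLEs. The heavy tail means genuine large effects are barely shrunk while
   noisy small ones collapse toward 0; the estimate always lies between 0
   and the MLE, so the sign never flips.
6. **Error control**: BH-adjusted p within contrast, plus a local FDR from
   an empirical null fit by central matching (location = median z, scale =
   MAD) with pi0 from the central +/- 1-scale region and the mixture
   density by kernel estimate; `lfdr = min(1, pi0 f0/f)`. With fewer than
   200 finite z-values the local FDR is not estimated (NA with a warning)
   and BH stands alone.

A PAC is flagged when `p < 0.01` and `|shrunk log2FC| > 0.5`; a second flag
additionally requires the host gene to carry at least two annotated PACs.
The order normalize -> log -> PC1 -> back-transform -> NB fit was an open
choice; it was fixed this way because the projection is meaningful on a
variance-stabilized scale, and is recorded here rather than exposed as an
option. The local FDR operates on Wald z-scores (p-value mode would be
equivalent up to the two-sided folding).

## Over-representation analysis

Given a query gene set, user-supplied collections (GMT format), and a
universe, each set is scored with the upper-tail hypergeometric
`P(X >= k)`, enrichment ratio `(k/n)/(K/N)`, BH FDR across sets, and an
inclusive `FDR <= 0.05` pass flag. No ontology payloads ship with the
package; tests and the pipeline use synthetic collections (e.g. the genes
with planted rhythms).

## The synthetic world

The generator's defaults state the world the tests run in:

* **Design**: 6 circadian timepoints x 5 replicates plus the
  sleep-deprivation arm (R0, R2, R4, R8 and the extra ZT8 control) x 5,
  with ZT6/ZT10/ZT14 shared between the arms — 55 unique libraries, as in
  the source design. Library sizes are drawn uniformly from 1.2-2.2
  million reads, deliberately straddling the 1.7M filter cutoff.
* **Genes**: 3 exons, a long terminal 3'UTR, both strands, non-overlapping,
  one chromosome. PASs per gene follow probabilities (0.55, 0.26, 0.12,
  0.07) over 1-4 — mean 1.71; the real-data mean reported for rat forebrain
  is 1.9, and the simulator's default approximates rather than matches it.
  The first PAS is always the annotated 3' terminus; extras fall into the
  3'UTR (50%), internal exons (15%), introns (15%) or the distal window
  (20%), always > 25 nt apart so planted sites can never co-cluster.
* **Counts**: `q(t) = m (1 + a cos(2*pi*(t - phi)/T))` per 10^7 reads, NB
  with `var = mu + alpha mu^2`, alpha = 0.05. 6% of PASs cycle at 24 h and
  5% at 12 h (the reported fractions), with relative amplitudes uniform on
  (0.2, 0.8) and phases uniform on [0, 24). 2.5% of PASs (the reported
  differentially expressed fraction) get a +1 log2 fold change in all
  recovery conditions. Base means are log-uniform on (20, 500) per 10^7.
* **Tags**: per-count Gaussian positional jitter (SD 3 nt), rounded and
  clamped at +/- 12 nt so distinct planted PASs never merge; clamping (vs
  resampling) puts negligible mass at the bound at SD 3.
* **Reads**: clean inserts of 30-100 nt never starting with `T`; a
  configurable fraction carries a 5' T-rich prefix of 5-20 nt built as T
  runs with isolated non-T bases spaced >= 4 apart and none in the last 3
  positions (>= 80% T overall). Under this construction the trimmer's only
  irreducible failure is a clean insert beginning `X,T,T,T` (~1.6%), so the
  >= 95% exact-recovery check is meaningful. Base qualities come from a
  two-component profile (~Q30 vs ~Q8) so the quality rule has both
  outcomes.

The generator does **not** emulate: alignment (mismatches, clipping,
multimapping), internal-priming artifacts, genomic sequence content (reads
are uniform random), chromosome structure beyond one contig, or
autocorrelated noise. A green test therefore establishes the statistical
pipeline's correctness on data satisfying its model assumptions, not
robustness to mapping artifacts.

## Reproducibility and degenerate inputs

One global seed fans out to per-stage seeds through a deterministic hash,
so a pipeline config reproduces every intermediate byte-for-byte; the run
manifest records a parameter hash (excluding the output path) and the md5
of every output. Degenerate inputs are defined rather than accidental:
empty reads are rejected by the quality filter with an error, constant
series give p = 1 in all detectors, all-tied series give JTK p = 1,
zero-total samples normalize to zero with a warning, all-zero features test
at p = 1, and p-values of 0 are clamped to the smallest positive double
before logs.

## Known limitations

* ARSER is replaced by cosinor regression as the third detector; on an
  evenly-sampled single-cycle design ARSER largely reduces to harmonic
  regression, and cosinor is exactly testable — but results on other
  designs may differ from ARSER-based stacks.
* The DE module reimplements the essential NB-Wald + heavy-tailed-shrinkage
  + empirical-null-lfdr core, not a full DE framework: no outlier
  (Cook's-distance) handling, no independent filtering, no covariates
  beyond the single nuisance direction.
* The consensus rule's sensitivity at moderate amplitudes is intrinsically
  low (see "Power of the consensus rule").
* Phase estimates mix two continuous detectors with JTK's 4 h grid; on
  noiseless data the combined phase can sit ~1 h off the truth, well within
  the 2 h tolerance used throughout.
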