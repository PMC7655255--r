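---
title: "Methods: exhaustive survival-signature search and evaluation"
author: "survSigSearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustive survival-signature search and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survSigSearch)
```

# The problem

Small prognostic expression signatures — a handful of genes whose weighted
expression stratifies patients into risk groups — are a standard tool in
cancer biostatistics. This package implements one complete discovery
pipeline for such signatures: starting from a genes-by-samples expression
matrix and per-sample survival records, it (i) removes genes that are zero
in most samples, (ii) screens the rest by univariate Cox regression,
(iii) exhaustively evaluates *every* combination of one to `k` screened
genes (k = 3 by default) as a multivariate Cox model, scoring each by the
ROC-AUC of its risk score against end-of-follow-up vital status on the
training cohort, and (iv) evaluates the winning signature on held-out and
cross-platform cohorts by Kaplan–Meier curves, the log-rank test,
Harrell's concordance index and ROC-AUC.

All survival statistics are implemented in this package from first
principles — they are the methodological core, not plumbing — and each one
is verified in the test suite against an independent oracle (hand
computations, pair enumeration, brute-force likelihood grids, and the
`survival` and `pROC` packages).

# Models and statistics

## Cox proportional-hazards fitting

For covariates $x_i$ (log-scale expression of the selected genes) the Cox
model assumes hazard $\lambda_i(t) = \lambda_0(t)\,e^{\beta^\top x_i}$.
`fitCox()` maximizes the Efron tie-corrected log partial likelihood by
Newton–Raphson. Per iteration every risk-set aggregate
($\sum_{j \in R(t)} e^{\eta_j}$ and its first two moments in $x$) is
obtained from suffix cumulative sums over samples sorted by time, so an
iteration costs $O(np^2)$; only tied death times take an explicit loop.

Numerical choices:

* **Ties.** Efron's correction is the default (it is the smaller-bias
  standard for data with tied event days); Breslow is available, and the
  two must agree on tie-free data — a property the tests assert.
* **Convergence.** The fit converges when the largest score component or
  parameter change falls below `tol` (1e-8) within `maxIter` (30)
  iterations, with step-halving whenever a Newton step fails to increase
  the likelihood.
* **Monotone likelihood.** With perfect separation the partial likelihood
  increases monotonically in $\beta$ and the MLE is infinite. The fit is
  flagged non-convergent when a coefficient passes $|\beta| > 20$, or when
  the score happens to vanish just inside that bound with an exploding
  standard error (SE > 100 log-hazard units — two orders of magnitude
  beyond any real expression effect). The exhaustive search *skips*
  flagged combinations rather than scoring them, so degenerate separation
  can neither win nor poison the argmax, and skipping is deterministic.
* **Zero-variance covariates** are unidentifiable; their coefficient is
  pinned at 0 (the likelihood is flat in them) and their SE reported as
  `NA`.
* **Overfit guard.** `fitCox()` refuses more than $n/5$ covariates; a
  single covariate is always allowed so that toy cohorts remain fittable.

## Kaplan–Meier, log-rank, C-index, AUC

`kmEstimate()` is the product-limit estimator over distinct event times;
censored observations only shrink risk sets. `logrankTest()` compares
observed group-1 deaths with their hypergeometric expectation at every
event time; the statistic is $\chi^2_1$. `concordanceIndex()` implements
Harrell's C: a pair is comparable iff the earlier time is an observed
event and times differ; score ties count 0.5; the SE is a Noether-type
normal approximation $\sqrt{c(1-c)/N_{\text{pairs}}}$, the 95% CI is
$c \pm 1.96\,\mathrm{SE}$ truncated to $[0,1]$, and the P-value tests
$c = 0.5$. `rocAUC()` is the Mann–Whitney AUC with DeLong's
structural-component variance for the CI and the test against 0.5.

The AUC label is end-of-follow-up vital status (death = positive) and the
predictor is the risk score; no time horizon enters. Time-dependent ROC is
deliberately out of scope. The CI estimators for AUC and C-index are
conventional choices among several asymptotically equivalent ones;
downstream decisions never depend on the specific estimator.

## The exhaustive search

Screened candidates are traversed as all subsets of size 1..k, size-major
and lexicographic within size, each combination addressed by a global rank
(combinatorial number system). This gives deterministic partitioning into
contiguous rank chunks: parallel workers, resumable chunked runs
(`chunk = c(i, w)` plus `mergeSearchResults()`), and the serial loop all
produce bit-identical results. The argmax tie-break is: higher training
AUC, then fewer genes, then lexicographic candidate order — realized
implicitly by only replacing the incumbent on a strictly larger AUC while
traversing in enumeration order, and explicitly by the same comparator
when merging chunks. At the full published scale (415 candidates, k = 3)
the traversal has 11,912,575 combinations; the tested scales are smaller
(tens of candidates), with the counting identities asserted in closed
form.

The objective is evaluated on the training cohort itself (fit and score on
the same samples), which is how such searches are run in practice;
validation cohorts are never touched during the search. Overfitting of the
objective is therefore expected — the validation AUC is always reported
separately.

## Risk score, stratification, projection

The risk score is the linear predictor
$\text{score}_i = \sum_g \hat\beta_g E_{gi}$. `stratifyMedian()` splits at
the median: samples sorted by (score, sample ID), lower half low-risk,
the extra sample of an odd cohort going to the low-risk group — a fixed,
documented convention, since "split evenly" underdetermines the boundary.
`projectSignature()` applies a signature to a platform missing some of its
genes by zeroing the missing terms and keeping the original coefficients;
refitting on the reduced gene set would answer a different question
(a new signature) and is intentionally not the default. Mean survival per
risk group is reported as the arithmetic mean of observed follow-up times;
the KM-based restricted mean would be a reasonable alternative but is not
the default.

## Coexpression screen and model comparison

`coexpressionScreen()` retains gene–marker pairs with Pearson $r > 0.6$
and two-sided t-test $P < 0.01$ by default. The threshold is *signed*:
strong negative correlates are excluded unless `absolute = TRUE`, because
the screen is meant to collect positively co-regulated partners of the
markers.

`resampleCompare()` draws repeated random 50% subsamples (1000 by default)
without replacement, scores every model on each subsample, and compares
models by two-sided Welch t-tests on their AUC vectors. Subsamples are
shared across models (a paired design, lower-variance than independent
draws; `paired = FALSE` gives the unpaired variant). Identical AUC vectors
(a model against itself) get P = 1 by convention. Subsamples lacking both
vital-status classes are redrawn with bounded retries and counted.

# The synthetic cohort generator

`simulateCohort()` produces the study conditions every stochastic test
runs under:

* expression per gene and sample is $\max(0, N(\mu, \sigma^2))$ with
  $\mu = 2$, $\sigma = 1$ on the log2 scale, plus a 20% zero-inflation
  fraction — clipping honours the $\log_2(x+1) \ge 0$ domain of
  normalized RNA-seq abundances;
* the planted signature (3 genes by default, coefficients 0.7675, 0.1726,
  −0.2466 — the scale of real published liver-cancer signature
  coefficients) drives an exponential event time with rate
  $\lambda_0 e^{\eta_i}$, where $\eta_i$ is computed from the *final*
  expression values so a Cox fit on the planted genes estimates exactly
  the generating coefficients;
* censoring is exponential and independent, its rate chosen by solving
  $\mathbb{E}[\lambda_c/(\lambda_c + \lambda_i)] = r$ over the realized
  per-sample hazards — exact in expectation under any covariate effect
  (the usual closed form at $\eta = 0$ is the special case), and verified
  by Monte-Carlo in the tests;
* defaults: 370 samples, 1000 genes, 65% censoring, baseline hazard
  1.5e-4/day. The sample count and censoring fraction mirror a typical
  liver-cancer RNA-seq cohort; the gene count is scaled down from the
  tens of thousands of a real transcriptome so a laptop-scale run
  finishes in seconds — prevalence filtering and screening behave
  identically, only the multiple-testing burden is smaller. The baseline
  hazard only sets the day scale (all rank-based statistics are invariant
  to it) and is chosen so observed follow-up lands on the one-to-two-year
  scale of real cohorts.

What the generator does **not** emulate: real marginal expression shapes
(FPKM-UQ is heavy-tailed, not truncated-Gaussian), gene–gene correlation,
informative censoring, and batch structure. Passing tests therefore
demonstrate correctness of the statistics and the search machinery under a
proportional-hazards world, not robustness to real-data pathologies.

`makeCrossPlatformView()` emulates re-measuring the same patients on a
platform lacking some signature genes: listed genes are removed and the
rest affinely distorted ($x \mapsto a x + b$ plus seeded noise, clipped at
0 to stay on the non-negative log scale — the one point where the affine
map could otherwise leave the valid domain).

# Design decisions worth recording

* **Prevalence filter boundary.** "Nonzero in at least half" is read as
  count $\ge \lceil n/2 \rceil$; the fraction is configurable since the
  even/odd boundary is a convention.
* **Train/validation split** is unstratified simple random sampling with
  sizes $\mathrm{round}(nf)$ and $n - \mathrm{round}(nf)$; published
  cohort splits that deviate from this (e.g. 187/183 of 370) reflect
  allocation details that cannot be reconstructed from "randomly
  allocated" and are not reproduced.
* **Reproducibility.** Every source of randomness flows through an
  explicit seed; package functions save and restore the caller's RNG
  state. The pipeline derives one deterministic sub-seed per stage from
  the root seed, so stage-wise reruns match full runs.
* **Cross-platform caveat.** Array-platform expression is accepted as-is
  after the log-scale check (`alreadyLog = TRUE`); no cross-platform
  rescaling is attempted before applying RNA-seq-derived coefficients.
  Projection across platforms is therefore conservative — the reported
  external AUC reflects both the signature and the platform shift.

# Problem sizes used by the tests

The acceptance-style checks run at the sizes their statistical guarantees
need and nothing larger: 100+ brute-force grid comparisons at $n \le 10$;
5000 null simulations of two 100-sample groups for log-rank calibration
(rejection rate asserted in [0.04, 0.06]); 20 seeds of $n = 2000$ for
coefficient recovery (|bias| < 0.05); 20 seeds of a 3-planted-plus-20-noise,
$n = 400$ search (trio recovered in ≥ 90%); 30 seeds of 1000-null-gene
screens (mean retention ≈ the nominal $m\alpha$); 100-seed null-AUC
calibration (mean within 0.5 ± 0.02); and a 200-repetition resampling
comparison of a true against a noise model (P < 0.001). The end-to-end
demonstration in `scripts/acceptance.R` uses the generator defaults
(370 × 1000).

# Known limitations

* No stratified or time-varying Cox models, no multi-group log-rank, no
  competing risks, no time-dependent ROC.
* The search is exhaustive by design; no greedy/heuristic fallback exists,
  so candidate counts much beyond ~500 at k = 3 require the chunked
  traversal and patience.
* The C-index SE is a pairs-as-independent approximation; it is slightly
  anti-conservative for heavily censored data. The CI never feeds back
  into any selection step.
* Subgroup analyses reuse the whole-cohort signature; they do not refit
  within subgroups.
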