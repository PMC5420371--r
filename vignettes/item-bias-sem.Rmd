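---
title: "Detecting item bias in ordinal questionnaires with semdif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting item bias in ordinal questionnaires with semdif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An item of a questionnaire is *biased* (shows differential item functioning,
DIF) with respect to a variable V — gender, age, treatment arm — when two
respondents with the same value of the measured trait T but different values
of V have different response distributions on that item.  Uniform bias is a
shift that does not depend on the trait level; nonuniform bias varies with
it.  Bias matters because group comparisons of scale scores then mix true
trait differences with measurement artifacts.

`semdif` implements two structural-equation-modeling routes to detect and
adjust for item bias in ordinal (e.g. 0–3 Likert) items:

* **Multigroup**: a one-factor model with mean structure fitted jointly to a
  reference and a focal group.  Uniform bias appears as a group difference
  in an item's intercept, nonuniform bias as a difference in its loading.
* **Multidimensional (restricted factor analysis)**: a single-group model
  with one or two correlated factors in which the violators enter as
  observed exogenous variables, correlated with the factors.  Uniform bias
  appears as a nonzero direct violator-to-item effect.  Nonuniform bias
  would require violator-by-trait interaction terms and is deliberately not
  implemented in this route.

## The underlying-variable model and Stage 1

Ordinal responses are modeled as discretizations of continuous underlying
variables: category k is observed when the underlying response falls between
thresholds \(\tau_k\) and \(\tau_{k+1}\).  Stage 1 estimates, per item, the
thresholds as probits of cumulative proportions, and, per pair of variables,
the polychoric (item–item), polyserial (item–covariate) and product-moment
(covariate–covariate) correlations by two-step maximum likelihood with
thresholds held fixed.  Each pair is screened for bivariate normality by the
RMSEA of the observed against model-implied cell counts (df = cells − 1 − 1;
pairs above 0.1 are flagged and surfaced in every downstream report, but the
procedure continues).

In the multigroup design the thresholds are constrained equal across groups
by estimating them from the pooled sample.  Both groups' underlying
locations and scales are then solved from their own margins against the
shared thresholds by least squares on the cumulative proportions, and the
whole solution is rescaled so the reference group is standardized (means 0,
SDs 1).  The focal group's means and SDs relative to that scale are data;
they carry the information about latent group differences.

Degenerate margins are handled deterministically: empty extreme categories
are collapsed into their neighbour, interior empty categories receive a 0.5
pseudo-count, and listwise deletion is applied with a message.  A polychoric
estimate at the correlation boundary (|ρ| = 0.999) is flagged.

Every Stage 1 estimate is a smooth function of sample proportions and
moments, so the asymptotic covariance Γ of the stacked moment vector is
assembled from per-observation influence contributions, with chains through
the pooled thresholds and the margin fits.  A stratified nonparametric
bootstrap (`acovMethod = "bootstrap"`) is available as a slower cross-check;
the test suite verifies the two routes agree.  Because the sample covariance
of ~100+ influence rows is noisy in its small eigenvalues, Γ is shrunk
toward its diagonal with a Ledoit–Wolf-style estimated weight (about 0.05 at
n = 2000).  This leaves the DWLS weights (the diagonal) untouched and
restores the calibration of the full-weight fit statistic; without it the
null mean of the chi-square exceeded its df by ~10%.

## Stage 2: DWLS fitting and fit evaluation

Models are fitted to the stacked moments by diagonally weighted least
squares: minimize \((s - \sigma(\theta))' W_d^{-1} (s - \sigma(\theta))\)
with \(W_d = \mathrm{diag}(\Gamma)\), via Levenberg–Marquardt with analytic
Jacobians.  Identification follows the reference-standardization convention;
moments that are identities under it (reference/single-group item means and
variances, standardized violator means and variances) are eliminated
together with the parameters they pin down, which leaves the degrees of
freedom unchanged — `countDf()` does the declared bookkeeping (per group,
p means + p(p+1)/2 covariances minus free parameter classes) and the fitter
asserts agreement.

Overall fit is summarized by the residual-based full-weight WLS chi-square:
the moment residuals at the DWLS estimates, weighted by \(\Gamma^{-1}\) with
the model tangent space projected out.  This statistic is asymptotically
central chi-square with the model df for any consistent estimator; the naive
unprojected quadratic form is not chi-square at DWLS estimates and was
measurably inflated.  RMSEA is
\(\sqrt{G \max(0, \chi^2 - df)/(df\,N)}\) with the 90% interval obtained by
inverting the noncentral chi-square in its noncentrality parameter;
conventional reads are close fit below .05 and reasonable fit below .08.
Parameter uncertainty uses robust sandwich standard errors with the full Γ.

Model-level comparisons (the bias-presence test of the No-Item-Bias versus
Measurement Model, and the equivalence check of the Final Model) are plain
chi-square differences, matching the printed bookkeeping convention of fit
tables (e.g. 126.4 − 50.64 = 75.76 on 12 df).  The 1-df candidate decisions
inside the iterative searches instead use a Satorra–Bentler-type scaled
difference of the DWLS discrepancies: for a single released parameter the
statistic divided by \(tr[(U_0 - U_1)\Gamma]\) is exactly asymptotically
\(\chi^2_1\), and because it touches Γ only through a trace it avoids the
shared inversion noise that otherwise overdisperses the 28-candidate scan
(measured null familywise flag rate ~10% before the change).

## The search and its decision rules

Both procedures follow the same four steps:

1. **Measurement Model** — no cross-group constraints (multigroup) or no
   violators (multidimensional); judged by RMSEA.
2. **No Item Bias Model** — full measurement invariance (loadings and
   intercepts equal across groups; focal factor mean and variance free), or
   all direct effects fixed at zero with free violator–factor correlations.
   Residual variances stay free per group: residual differences are not
   treated as bias and do not affect latent-difference estimates, and this
   choice reproduces the standard df arithmetic (28 → 40 for seven items).
   In the multidimensional route an RMSEA of at least .08 here is reported
   as the global indication of bias, but it gates nothing.
3. **Iterative search** — greedy forward: release each remaining constraint
   one at a time, take the candidate with the largest fit improvement,
   accept if its scaled 1-df test has p < .001, repeat; released parameters
   stay free; ties break to the lower item index, intercept before loading.
   Candidate fits that fail to converge are skipped with a log entry.  The
   significance gate is deliberately strict (α = .001) to guard against
   false positives at large N.
4. **True differences / associations** — from the Final Model (adjusted)
   and the No-Item-Bias Model (unadjusted): the standardized latent group
   difference \(d = \kappa_{foc}/\sqrt{(\phi_{ref}+\phi_{foc})/2}\), or the
   factor–violator correlations, with Wald p values.

Effect sizes: uniform bias d = intercept difference over the pooled
underlying SD (equal-weighted across groups); nonuniform bias
d = (loading difference) × (factor-mean difference) over the pooled SD —
by its definition this is zero whenever the latent means coincide, which is
a property of the published formula, implemented as written; direct-effect
bias r = the standardized direct effect.  Importance gates: |d| > 0.2,
|r| > 0.1, each together with p < .001.

## The synthetic-data generator

`makeHadsLikeSpec()` provides scenarios emulating a HADS-like instrument:
seven items per subscale with four categories, loadings 0.6–0.8 on a
unit-variance underlying scale, mildly skewed thresholds (symptom items are
right-skewed), a two-factor version with 14 items and factor correlation
0.8, a binary violator with prevalence 0.41 and a continuous violator with
mean 50 and SD 18 whose default factor correlations (−0.16/−0.04 and
−0.24/0.01) mirror the magnitudes seen in primary-care samples.  Two-group
scenarios default to a focal latent mean of −0.3.  Bias is injected on the
underlying response before discretization: uniformly as size × violator
(binary violators as 0/1 indicators, so the size is the shift of the
violator group; continuous violators on their unit-SD scale, so the size is
a standardized effect), and nonuniformly as size × violator × factor score,
i.e. a loading increment.  `simulateOrdinal(..., returnLatent = TRUE)`
exposes the continuous layer so injection sizes are directly testable.

What the generator does *not* emulate: missingness beyond MCAR deletion,
acquiescence or response styles, longitudinal dependence, floor effects
beyond what the thresholds produce, and real HADS category distributions
(the study's raw data are not public, so thresholds are conventional).
Passing simulation suites therefore demonstrates statistical correctness of
the machinery under the stated graded-response model, not robustness to
every real-data pathology — the bivariate-normality screen exists precisely
to flag departures on real data.

## Problem sizes used by the test and acceptance suites

Simulation suites are sized for a single-CPU run: type-I control uses 120
no-bias multigroup replicates (7 items, n = 1000 per group) and 100
multidimensional replicates (14 items, 2 violators, n = 1000); power and
localization use 60 replicates of a 0.5-SD uniform bias (n = 1000 per
group) checked by both routes on the same data; parameter recovery uses
n = 5000; the chi-square calibration check uses 40 replicates at n = 500
per group.  The acceptance script uses the same designs with 100/80/50
replicates.

## Known limitations

* The multidimensional route detects uniform bias only.
* Item bias is only identifiable relative to the majority of a factor's
  items: when most items carry the same-sign, same-size bias, the model
  attributes the common shift to the factor-violator association and flags
  the clean minority with flipped signs.  Real bias patterns of mixed sign
  and size (as in the motivating application) are localizable; a uniformly
  contaminated scale is not, by any anchor-free method.
* The exact estimator PRELIS/LISREL used for focal-group underlying moments
  under equal thresholds is not published; the least-squares margin fit
  used here is one defensible choice, and the df/RMSEA arithmetic it feeds
  reproduces the published accounting exactly.
* The full-weight statistic relies on an estimated Γ; below n ≈ 300 per
  group its calibration degrades and the bootstrap acov is recommended.
* Binary violators are treated as numeric observed variables (no
  thresholding) in Stage 1, matching the restricted-factor-analysis
  treatment of gender; an ordinal-violator treatment is out of scope.
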