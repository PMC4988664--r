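---
title: "Methods and design of disurv"
author: "disurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of disurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disurv)
```

disurv is a toolkit for right-censored clinical survival data.  It covers
the classical descriptive and inferential workflow — Kaplan-Meier curves,
weighted log-rank comparisons, kernel-smoothed hazard rates, Cox regression,
contingency-table tests — and a discrete-time, individual-level survival
predictor built on a single-hidden-layer neural network.  This vignette
explains each model, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-cohort generator
does and does not emulate.

## Data model

A `survival_dataset` holds one record per subject: a non-negative follow-up
time, a censorship indicator (0 = censored, 1 = event) and arbitrary
covariates.  `load_csv()` maps CSV columns onto these roles and can remap
other status codings (`event_code`, `censor_code`).  Rows with missing
covariate values are dropped with a reported count: survival methods have no
canonical missing-data treatment, and silent imputation would be worse than
an explicit, logged exclusion.  Zero follow-up times are accepted (they
contribute to risk sets at time 0 only).

`stratify()` cuts numeric covariates at user breakpoints.  Clinical range
tables are often printed with shared endpoints ("39 to 45, 45 to 55"); the
implemented convention resolves the ambiguity by closing the first interval
on both ends and making every later interval left-open/right-closed, so a
boundary value belongs to the earlier stratum.  The convention is
switchable (`right = FALSE`).

## Kaplan-Meier estimation

`fit_km()` computes the product-limit estimate over the distinct observed
event times $t_i$,

$$\hat S(t) = \prod_{t_i \le t} \Bigl(1 - \frac{m_i}{n_i}\Bigr),$$

with $m_i$ events at $t_i$ and $n_i$ subjects at risk just before $t_i$.
Subjects censored exactly at an event time are still at risk there (events
precede censorings) — the standard risk-set convention.  Choices that the
classical presentation leaves open:

* **Confidence band.** The default is the Greenwood variance on the
  log-survival scale with normal quantiles, the convention of the survival
  package; `conf_type = "plain"` gives the untransformed symmetric band.
  Both are clipped to $[0, 1]$ and become undefined once $\hat S = 0$.
* **Median survival.** The smallest event time with $\hat S \le 0.5$
  (`NA` when the curve never reaches 0.5).  Taking the left endpoint of a
  plateau keeps the definition deterministic and consistent with step-function
  semantics.
* **Median follow-up.** The reverse Kaplan-Meier estimate: the same
  estimator applied with the status indicator flipped, i.e. the median of
  the censoring distribution — the standard clinical convention for
  "how long were patients followed".

`risk_table()` counts subjects with observed time at least each grid point,
the table printed beneath survival and hazard plots.

## Weighted log-rank comparisons

`compare_curves()` tests equality of $k \ge 2$ survival curves.  At each
distinct pooled event time the observed events per group are compared with
the expectation under a common hazard, $e_{gi} = n_{gi} m_i / n_i$, and the
per-time hypergeometric variance.  The accumulated statistic uses a
per-time weight:

| scheme | weight $w_i$ | emphasis |
|---|---|---|
| log-rank | $1$ | proportional hazards alternatives |
| Peto-Peto | pooled left-continuous KM $\hat S(t_i^-)$ | early differences |
| Tarone-Ware | $\sqrt{n_i}$ | intermediate |

For $k$ groups the statistic is the quadratic form of the first $k - 1$
weighted $(O - E)$ components in the (generalized) inverse of their
covariance, with $k - 1$ degrees of freedom; for $k = 2$ this reduces
algebraically to the scalar formula, which the tests verify.  A printed
variance formula that nests a second summation inside the per-time term was
read as the standard per-time hypergeometric variance summed over event
times — the only reading under which the statistic is dimensionally a
chi-square.

The two-group **odds ratio** is reported as
$(O_X/E_X)\,/\,(O_Y/E_Y)$ on the *unweighted* observed and expected counts
— the ratio of relative event rates familiar from survdiff-style output.
The quantity is named but not defined in most presentations; this definition
is flagged here and in the function documentation.

No continuity correction is applied to the comparison P values.

## Hazard-rate estimation

`nelson_aalen()` returns the increments $m_i/n_i$ of the cumulative-hazard
estimator.  `smooth_hazard()` convolves them with a fixed-bandwidth kernel:

$$\hat h(t) = \frac1b \sum_i K\!\Bigl(\frac{t - t_i}{b}\Bigr)\,
  \widehat{\Delta H}(t_i),$$

with the Epanechnikov kernel $K(x) = \tfrac34(1 - x^2)$ on $[-1, 1]$ in the
interior.  Within one bandwidth of 0 or of $t_D$ (the largest event time)
the kernel is replaced by a second-order asymmetric boundary kernel on
$[-1, q]$, built as $K(x)(\alpha + \beta x)$ with $\alpha, \beta$ solving
the moment conditions $\int K_q = 1$, $\int x K_q = 0$; at $q = 1$ it
reduces to the interior kernel, and the right boundary uses the reflection
$x \mapsto -x$.  This is the standard boundary-bias correction for kernel
hazard estimation.

Numerical notes, established while validating the implementation:

* The boundary correction is indexed by the **estimation point** (the
  bias-correcting convention).  Audited directly: this convention does not
  conserve the integral of the curve exactly — the alternative
  increment-indexed convention would, but at the cost of a ~50% upward bias
  at the very edge.  With a bandwidth around a tenth of the time axis
  (e.g. bandwidth 3 on a 38-month recurrence cohort) the integral of
  $\hat h$ matches the total Nelson-Aalen mass to about 1%; the deviation
  grows with $b / t_D$.  The tests check conservation at that realistic
  ratio.
* Boundary kernels have a negative lobe, so raw estimates can dip slightly
  below zero near the edges; estimates are clipped at zero.
* Defaults: 101 equally spaced grid points on $[0, t_D]$; the bandwidth is
  always user-supplied (fixed-bandwidth estimation only — no automatic or
  locally adaptive bandwidth selection).  The optional 95% band uses the
  asymptotic variance
  $b^{-2} \sum_i K^2\{(t - t_i)/b\}\, m_i / \{n_i (n_i - m_i)\}$.

The curve is annotated with its maximum and the time it is reached.  (The
quantity is sometimes labelled a maximum hazard *ratio*; dimensionally it is
a rate — events per time unit — and is implemented as the curve maximum.)

## Cox proportional-hazards regression

`fit_cox()` fits $h(t, X) = h_0(t)\exp(\sum_i \beta_i X_i)$ by partial
likelihood, via the survival package's Newton-Raphson from $\beta = 0$ with
convergence at a relative log-likelihood change below $10^{-9}$ (at most 25
iterations).  Tied event times are handled by Breslow, Efron or the exact
discrete likelihood.  `partial_loglik()` is a from-scratch evaluation of all
three likelihoods — the exact denominator is the elementary symmetric
polynomial of the risk weights, computed by a stable recurrence — exposed so
that the fitting route can be checked against brute-force enumeration; the
test suite does exactly that, and also verifies that the analytic score
vanishes at the fitted coefficients and that all three corrections coincide
on tie-free data.

Other inference choices:

* Per covariate: Wald test, 95% normal-quantile confidence interval, hazard
  ratio $e^{\beta}$.  The global "goodness of fit" chi-square is the
  likelihood-ratio test against the null model — the headline statistic of
  standard Cox output (a Wald or score global test would be equally
  defensible; LRT was chosen and is reported as such).
* Categorical covariates are reference-coded against the first level in
  sorted order; `strata` fits separate baseline hazards with a shared
  $\beta$.
* `stepwise_select()` searches backward, forward or in both directions,
  guided by AIC on the partial likelihood (via stepAIC).  The selection
  criterion is a documented design choice: a P-value-threshold search would
  also fit the classical description, but AIC is the convention of the
  R ecosystem this workflow mirrors.
* `ph_assumption_test()` is the scaled-Schoenfeld-residual test against
  Kaplan-Meier-transformed time, per covariate and globally.  Simulation
  under a proportional effect shows the nominal 5% rejection rate (the
  suite runs 500 replicates at n = 1000), and a sign-reversing effect is
  detected with p < 0.01 at n = 1000.

## Contingency tables

`build_table()` cross-tabulates two categorical covariates with marginals;
proportions are displayed either as percentages or on a 0–1 scale, and the
style never changes counts or tests.  Tests: Pearson chi-square of
independence (no Yates correction by default, switchable), the two-sided
Fisher exact test (probability ordering of hypergeometric tables, the R
convention), and McNemar's $(b - c)^2/(b + c)$ on the discordant cells of a
paired 2x2 table (no continuity correction by default; undefined and
reported as such when $b + c = 0$).  The Fisher implementation is verified
against full hypergeometric enumeration for every 2x2 table with total at
most 30.

## The discrete-time network predictor

The predictor discretises follow-up into $G$ intervals containing equal
numbers of events (`discretize()`): boundaries sit at event-time quantiles,
ties are never split, any remainder goes to the earliest intervals, and
because events concentrate early, early intervals come out shorter.  Each
subject is encoded (`encode_targets()`) as a length-$G$ hazard target
vector:

* 0 for every interval up to and including the interval of the observed
  time;
* for later intervals: 1 if the subject's event was observed, else the
  cohort interval hazard $m_t/n_t$.

A single-hidden-layer network (logistic activations at both layers, one
input per predictor, $G$ outputs) is trained on these targets with
sum-of-squares loss and weight decay.  `train_ann()` runs the 10-fold
scheme: subjects are shuffled once under the run seed into ten equal folds;
in iteration $i$ fold $i$ is the test set, fold $i + 1$ (cyclically) the
validation set, and the remaining eight folds train the network.  Every
candidate hidden-layer size is trained with early stopping on validation
loss; the size with the highest mean validation accuracy wins, its mean
test-fold accuracy is reported as `cv_accuracy`, and the final network is
retrained on the full data.  Accuracy is

$$\mathrm{ACC} = \frac{\sum_{i=1}^{N} \bigl(G - |T_i - T_i'|\bigr)}{G\,N}
  \in [1/G,\, 1],$$

over actual and estimated survival intervals.  A predicted curve is
reconstructed by the discrete product
$\hat S(t) = \prod_{i < t} (1 - \hat h_i)$, and — applied to the cohort
hazards $m_t/n_t$ themselves — this product reproduces the Kaplan-Meier
curve exactly at the interval boundaries, which the tests assert.

Training details are deliberate design choices, surfaced as arguments:
standardization of the design matrix fitted on the training folds only
(necessary for stable optimization), weight decay $10^{-3}$, an iteration
budget of 500 with validation checks every 100 and patience 200 (the
optimizer has no native early stopping, so training proceeds in
warm-started chunks), candidate hidden sizes $\{2, 4, 8, 12, 16, 20, 24,
32\}$, and fold assignment without event-status stratification.  Identical
seeds give bitwise-identical models; models serialize to JSON and back
without changing a prediction.

**Decoding the estimated interval.** The encoding places the first 1
strictly *after* the event interval, so the reconstructed curve of a subject
dying in interval $k$ first drops at interval $k + 1$.  The estimated
interval $T'$ therefore is one less than the first interval whose
reconstructed survival falls below 0.5 (floored at 1; $G$ when the curve
never crosses).  Under the `hazard_at_event = TRUE` variant — which moves
the 1 to the event interval itself — the unshifted first-drop rule applies.
This makes a deterministic cohort decode to perfect accuracy, which the
tests check.

**A structural limitation, stated plainly.**  Because targets stay at 1 for
every interval after an observed event, the least-squares optimum of the
network at a covariate pattern is the pattern's *mortality-status*
expectation $P(\text{dead by interval } t)$ — a CDF-like quantity — rather
than the conditional hazard; only the censored branch injects genuine
hazards.  The cumulative product consequently overstates mortality whenever
event rates are non-negligible: on generator cohorts the reconstructed
curves sit systematically below the generating truth (mean absolute error
around 0.15 at the validation settings below), although the *ordering* of
pattern curves, the interval decoding and the accuracy score are unaffected
in practice.  The consistent alternative — excluding post-event intervals
from the loss — is a different method and is out of scope.  Validation
reports the measured error rather than hiding it.

## The synthetic-cohort generator

`generate_cohort()` draws discrete-time data by a geometric walk over $G$
intervals: a subject at risk in interval $t$ fails with its pattern hazard,
otherwise censors with probability `censor_prob`, otherwise advances;
survivors past $G$ are censored at $G$.  Covariates are independent
Bernoulli(0.5) indicators whose effects act on the logit of the interval
hazard by default (log odds ratios), or via `link = "cloglog"` as log
*hazard* ratios (the grouped proportional-hazards model — the right truth
scale when validating Cox estimates).  The generator returns the exact
per-pattern interval hazards and survival curves alongside the data, so
every estimator can be checked against known truth.

What it does not emulate: continuous event times within an interval
(recorded times are interval indices), covariate-dependent or informative
censoring, time-varying effects (except when built manually, as in the
PH-diagnostic power test), correlated covariates, and measurement error.
Passing tests therefore demonstrate correctness of the estimators under the
discrete-hazard data-generating process, not robustness to the many ways
real cohorts violate it.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run every experiment at these
sizes, chosen once as realistic for the questions asked: exhaustive
product-limit enumeration over all censoring patterns of up to 8 subjects;
every 2x2 Fisher table with total at most 30; type-I error of the three
comparison tests from 1000 null replicates of two 200-subject arms
(nominal 0.05, observed within [0.03, 0.07]); Cox recovery of a log-hazard
effect of 0.7 at n = 2000 over 200 seeds (20 intervals, baseline hazard
0.03, 1% interval censoring; the estimate falls within three standard
errors of truth in at least 95% of seeds); kernel mass conservation on the
85-subject first-recurrence cohort at bandwidth 3; and the network
predictor at n = 2000, G = 8 with hidden-size grid {4, 8, 16} for the
error measurement and a single size 8 for the 20-seed ordering experiment.

## Command line

`inst/cli/disurv` exposes the same operations as subcommands (`km`,
`compare`, `hazard`, `cox`, `crosstab`, `ann-train`, `ann-predict`,
`simulate`) writing CSV/JSON tables and optional PNG/PDF/EPS plots; a
`key = value` config file can supply any option, with explicit flags taking
precedence.  Exit codes: 0 success, 2 usage error, 3 validation error,
4 numerical failure.  Identical configuration and seed give byte-identical
tables.
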