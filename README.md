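# disurv

Survival analysis for right-censored clinical data in R: the classical
workflow — Kaplan-Meier curves, weighted log-rank comparisons,
kernel-smoothed hazard rates, Cox proportional-hazards regression,
contingency-table tests — plus a discrete-time, individual-level survival
predictor based on a single-hidden-layer neural network.  It is written for
clinical researchers and biostatisticians who want the standard estimators,
their diagnostics and a machine-learning predictor behind one consistent
data model, with a scriptable command line.

## What it computes

For a cohort of subjects with follow-up times and a censorship indicator
(0 = censored, 1 = event):

* **Kaplan-Meier** product-limit estimate
  `S(t) = prod_{t_i <= t} (1 - m_i/n_i)` with Greenwood confidence bands
  (log scale by default), median survival, reverse-KM median follow-up and
  number-at-risk tables.
* **Curve comparison** over k groups by the weighted log-rank family —
  log-rank (w = 1), Peto-Peto (w = pooled left-continuous KM) and
  Tarone-Ware (w = sqrt(n)) — as a chi-square on k - 1 df, with the O/E
  odds ratio for two groups.
* **Hazard rate** by fixed-bandwidth Epanechnikov kernel smoothing of the
  Nelson-Aalen increments, with Gasser-Müller boundary kernels near the
  edges and the curve maximum annotated.
* **Cox regression** `h(t, X) = h0(t) exp(sum beta_i X_i)` with Breslow,
  Efron or exact tie handling, Wald inference, likelihood-ratio fit test,
  AIC-guided stepwise selection, stratified baselines and the
  scaled-Schoenfeld proportional-hazards diagnostic.  The partial
  log-likelihood of all three tie corrections is also exposed directly
  (`partial_loglik()`) for verification.
* **Contingency tables** with marginals, SPSS-percent or SAS-unit display,
  Pearson chi-square, two-sided Fisher exact and McNemar tests.
* **Discrete-time ANN predictor**: follow-up split into G intervals with
  equal event counts; each subject encoded as a per-interval hazard target
  vector (zeros through the observed interval, then 1 if the event was
  observed or the cohort hazard m_t/n_t if censored); a logistic
  single-hidden-layer network trained under 10-fold cross-validation with
  hidden-size search; accuracy
  `ACC = sum(G - |T - T'|) / (G N)`; and individual survival curves
  reconstructed by `S(t) = prod_{i<t} (1 - h_i)`.
* **Synthetic cohorts** from known per-interval discrete hazards with
  covariate effects and independent censoring (`generate_cohort()`), with
  the generating truth returned for validation.

## A worked example

```r
library(disurv)

# bladder-cancer first recurrences: 85 subjects, treatment arm as group
bl <- survival::bladder[survival::bladder$enum == 1, ]
ds <- survival_dataset(bl$stop, bl$event,
                       data.frame(rx = factor(bl$rx, labels = c("Placebo", "ThioTEPA")),
                                  number = bl$number, size = bl$size))

fit <- fit_km(ds, group = "rx")
compare_curves(ds, "rx", "log-rank")
```

```
Survival curve comparison (log-rank)
    level  n events expected
  Placebo 47     29    24.91
 ThioTEPA 38     18    22.09

Chisq = 1.521 on 1 df, p = 0.2175
Odds ratio (O/E vs O/E): 1.428
```

The placebo arm shows 29 recurrences against 24.9 expected under a common
hazard, ThioTEPA 18 against 22.1; the log-rank chi-square of 1.52 (p =
0.22) does not reject equality of the curves, and the O/E odds ratio of
1.43 points the excess toward placebo.  The smoothed hazards behind the
same cohort, at the bandwidth of 3 months used for such recurrence data:

```r
smooth_hazard(survival_dataset(ds$time[ds$covariates$rx == "Placebo"],
                               ds$status[ds$covariates$rx == "Placebo"]),
              bandwidth = 3)
```

```
<hazard_curve> bandwidth = 3, 101 grid points on [0, 35]
maximum hazard 0.2807 at t = 35
```

Training the discrete-time predictor on a synthetic cohort with known
truth:

```r
sim <- generate_cohort(2000, hazards = c(0.25, 0.2, 0.15, 0.12, 0.1, 0.08, 0.08, 0.08),
                       effects = c(x1 = 1.0, x2 = 0.5), censor_prob = 0.05, seed = 101)
model <- train_ann(sim$data, 8, hidden_grid = c(4, 8, 16), seed = 101)
predict_survival(model, list(x1 = 1, x2 = 0))
```

```
<ann_survival_model> G = 8, hidden size = 4, cv accuracy = 0.8051
```

`cv_accuracy` is the mean test-fold interval accuracy of the selected
network (1 = every subject's survival interval predicted exactly, 1/G =
maximally wrong).  `predict_survival()` returns the per-interval hazards,
the reconstructed survival curve and the estimated survival interval for
one covariate pattern.

## Command line

```sh
inst/cli/disurv km       --input data.csv --time-col time --status-col status --group arm --risk-table --ci
inst/cli/disurv compare  --input data.csv --time-col time --status-col status --group arm --test logrank
inst/cli/disurv hazard   --input data.csv --time-col time --status-col status --bandwidth 3
inst/cli/disurv cox      --input data.csv --time-col time --status-col status --covariates age,sex --ties efron --stepwise backward
inst/cli/disurv ann-train --input data.csv --time-col time --status-col status --groups 8 --seed 1
```

Each task writes CSV/JSON tables (and optional PNG/PDF/EPS plots) into
`--out-dir`; identical configuration and seed give byte-identical tables.

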