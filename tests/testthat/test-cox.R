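test_that("the two-subject partial log-likelihood has its closed form", {
  ds <- survival_dataset(c(1, 2), c(1, 1), data.frame(x = c(1, 0)))
  for (b in c(-1, -0.3, 0, 0.5, 2))
    expect_equal(partial_loglik(ds, "x", b), b - log(exp(b) + 1))
})

test_that("the null value and the fitted value agree with the fitting routine", {
  sim <- generate_cohort(150, rep(0.2, 6), effects = c(x = 0.6),
                         censor_prob = 0.1, seed = 3)
  for (ties in c("breslow", "efron", "exact")) {
    fit <- fit_cox(sim$data, "x", ties = ties)
    expect_equal(partial_loglik(sim$data, "x", 0, ties = ties),
                 fit$loglik_null, tolerance = 1e-8)
    expect_equal(partial_loglik(sim$data, "x", fit$coefficients, ties = ties),
                 fit$loglik_fit, tolerance = 1e-8)
    # maximality: any perturbation of 0.1 lowers the likelihood
    for (delta in c(-0.1, 0.1))
      expect_lt(partial_loglik(sim$data, "x", fit$coefficients + delta,
                               ties = ties),
                fit$loglik_fit)
  }
})

test_that("the fitted coefficient maximizes the partial likelihood (6 subjects)", {
  ds <- survival_dataset(c(2, 4, 5, 7, 9, 12), c(1, 1, 0, 1, 1, 1),
                         data.frame(z = c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1)))
  fit <- fit_cox(ds, "z", ties = "breslow")
  opt <- optimize(function(b) cox_loglik_brute(ds$time, ds$status,
                                               ds$covariates$z, b, "breslow"),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
})

test_that("symmetric event patterns give a zero coefficient and unit hazard ratio", {
  ds <- survival_dataset(rep(c(1, 3, 4, 6), 2), rep(c(1, 1, 0, 1), 2),
                         data.frame(g = rep(c("a", "b"), each = 4)))
  fit <- fit_cox(ds, "g")
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-7)
  expect_equal(unname(fit$hazard_ratios), 1, tolerance = 1e-7)
})

test_that("without tied event times all three tie methods coincide", {
  set.seed(8)
  n <- 40
  ds <- survival_dataset(sample(seq(1, 400), n), rbinom(n, 1, 0.8),
                         data.frame(x = rnorm(n), y = rbinom(n, 1, 0.5)))
  fits <- lapply(c("breslow", "efron", "exact"), function(tt)
    fit_cox(ds, c("x", "y"), ties = tt)$coefficients)
  expect_equal(fits[[1]], fits[[2]], tolerance = 1e-8)
  expect_equal(fits[[2]], fits[[3]], tolerance = 1e-8)
})

test_that("tie-corrected likelihoods match brute-force tie sums on small data", {
  # every dataset with <= 6 subjects and <= 3 tied deaths in the suite below
  tie_sets <- list(
    list(time = c(1, 1, 2, 3), status = c(1, 1, 1, 0)),
    list(time = c(1, 1, 1, 2, 3), status = c(1, 1, 1, 1, 1)),
    list(time = c(2, 2, 2, 5, 5, 7), status = c(1, 1, 0, 1, 1, 1)),
    list(time = c(1, 2, 2, 2, 4, 4), status = c(0, 1, 1, 1, 1, 0)))
  set.seed(5)
  for (cfg in tie_sets) {
    n <- length(cfg$time)
    x <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    ds <- survival_dataset(cfg$time, cfg$status,
                           data.frame(x1 = x[, 1], x2 = x[, 2]))
    for (beta1 in list(c(0, 0), c(0.5, -0.7), c(-1.2, 0.3)))
      for (ties in c("breslow", "efron", "exact"))
        expect_equal(partial_loglik(ds, c("x1", "x2"), beta1, ties = ties),
                     cox_loglik_brute(cfg$time, cfg$status, x, beta1, ties),
                     tolerance = 1e-12)
  }
})

test_that("the exact correction equals subset enumeration with four tied deaths", {
  time <- c(3, 3, 3, 3, 5, 6)
  status <- c(1, 1, 1, 1, 1, 0)
  set.seed(6)
  x <- matrix(rnorm(6), ncol = 1)
  ds <- survival_dataset(time, status, data.frame(x = x[, 1]))
  for (b in c(-0.8, 0, 0.4, 1.1))
    expect_equal(partial_loglik(ds, "x", b, ties = "exact"),
                 cox_loglik_brute(time, status, x, b, "exact"),
                 tolerance = 1e-12)
})

test_that("the score vanishes at the fitted coefficients", {
  sim <- generate_cohort(300, rep(0.15, 8), effects = c(x = 0.7, y = -0.4),
                         censor_prob = 0.1, seed = 7)
  fit <- fit_cox(sim$data, c("x", "y"), ties = "efron")
  X <- as.matrix(sim$data$covariates[c("x", "y")])
  g <- cox_score_efron(sim$data$time, sim$data$status, X, fit$coefficients)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("fit diagnostics respect the likelihood-ratio identities", {
  sim <- generate_cohort(200, rep(0.2, 6), effects = c(x = 0.8),
                         censor_prob = 0.1, seed = 9)
  fit <- fit_cox(sim$data, "x")
  expect_gte(fit$loglik_fit, fit$loglik_null)
  expect_equal(fit$lrt$statistic, 2 * (fit$loglik_fit - fit$loglik_null))
  expect_gte(fit$lrt$statistic, 0)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))
  expect_true(all(fit$ci[, "lower"] <= fit$coefficients,
                  fit$coefficients <= fit$ci[, "upper"]))
  expect_true(all(diag(fit$covariance) >= 0))
})

test_that("degenerate inputs are rejected with informative errors", {
  ds <- survival_dataset(1:4, rep(1L, 4), data.frame(k = rep(1, 4)))
  expect_error(fit_cox(ds, "k"), "constant")
  nz <- survival_dataset(1:4, rep(0L, 4), data.frame(x = rnorm(4)))
  expect_error(fit_cox(nz, "x"), "event")
  expect_error(fit_cox(survival_dataset(1:4, rep(1L, 4),
                                        data.frame(x = 1:4)), "nope"),
               "covariate")
  expect_error(partial_loglik(survival_dataset(1:3, rep(1L, 3),
                                               data.frame(x = 1:3)),
                              "x", c(1, 2)),
               "length")
})

test_that("backward elimination keeps a real effect and drops pure noise", {
  sim <- generate_cohort(500, rep(0.12, 10), effects = c(signal = 0.9),
                         censor_prob = 0.05, seed = 15)
  covs <- sim$data$covariates
  set.seed(16)
  covs$noise <- rnorm(500)
  ds <- survival_dataset(sim$data$time, sim$data$status, covs)
  sel <- stepwise_select(ds, c("signal", "noise"), direction = "backward")
  expect_true("signal" %in% sel$selected)
  expect_false("noise" %in% sel$selected)
})

test_that("forward selection from all-noise candidates stays near the null model", {
  sim <- generate_cohort(500, rep(0.12, 10), censor_prob = 0.05, seed = 25)
  set.seed(26)
  covs <- data.frame(n1 = rnorm(500), n2 = rnorm(500), n3 = rbinom(500, 1, 0.5))
  ds <- survival_dataset(sim$data$time, sim$data$status, covs)
  sel <- stepwise_select(ds, c("n1", "n2", "n3"), direction = "forward")
  null_ll <- partial_loglik(ds, "n1", 0)
  aic_sel <- -2 * sel$loglik_fit + 2 * length(sel$coefficients)
  aic_null <- -2 * null_ll
  expect_lte(length(sel$selected), 1L)
  expect_lt(aic_sel - aic_null, 2)
})

test_that("both-direction selection ends at an AIC fixed point", {
  sim <- generate_cohort(400, rep(0.15, 8), effects = c(a = 0.8, b = 0),
                         censor_prob = 0.05, seed = 35)
  covs <- sim$data$covariates
  set.seed(36)
  covs$c <- rnorm(400)
  ds <- survival_dataset(sim$data$time, sim$data$status, covs)
  sel <- stepwise_select(ds, c("a", "b", "c"), direction = "both")
  aic <- function(covset) {
    if (length(covset) == 0) return(-2 * partial_loglik(ds, "a", 0))
    f <- fit_cox(ds, covset)
    -2 * f$loglik_fit + 2 * length(f$coefficients)
  }
  base <- aic(sel$selected)
  for (v in setdiff(c("a", "b", "c"), sel$selected))   # no add improves
    expect_gte(aic(c(sel$selected, v)), base - 1e-8)
  for (v in sel$selected)                              # no drop improves
    expect_gte(aic(setdiff(sel$selected, v)), base - 1e-8)
})

test_that("a single-covariate model has matching per-variable and global PH tests", {
  sim <- generate_cohort(200, rep(0.2, 6), effects = c(x = 0.6),
                         censor_prob = 0.1, seed = 45)
  fit <- fit_cox(sim$data, "x")
  ph <- ph_assumption_test(fit)
  expect_equal(nrow(ph), 2L)
  expect_equal(ph$chisq[1], ph$chisq[ph$term == "GLOBAL"], tolerance = 1e-8)
})

test_that("a sign-reversing effect is flagged by the PH diagnostic", {
  # hazard effect +1 in intervals 1..4, -1 in 5..8
  set.seed(55)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  time <- rep(8L, n); status <- rep(0L, n); alive <- rep(TRUE, n)
  for (t in 1:8) {
    eff <- if (t <= 4) 1 else -1
    h <- plogis(qlogis(0.12) + eff * x)
    dies <- alive & (runif(n) < h)
    time[dies] <- t; status[dies] <- 1L; alive[dies] <- FALSE
  }
  ds <- survival_dataset(time, status, data.frame(x = x))
  ph <- ph_assumption_test(fit_cox(ds, "x"))
  expect_lt(ph$p_value[ph$term != "GLOBAL"], 0.01)
})

test_that("under proportional hazards the PH test rejects at its nominal rate", {
  reps <- 500
  rej <- 0L
  for (r in seq_len(reps)) {
    sim <- generate_cohort(1000, rep(0.15, 8), effects = c(x = 0.6),
                           censor_prob = 0.05, seed = 1000 + r,
                           link = "cloglog")
    fit <- fit_cox(sim$data, "x")
    ph <- ph_assumption_test(fit)
    rej <- rej + (ph$p_value[ph$term == "GLOBAL"] < 0.05)
  }
  rate <- rej / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("stratified baselines are honoured through the strata argument", {
  sim <- generate_cohort(300, rep(0.15, 8), effects = c(x = 0.7),
                         censor_prob = 0.05, seed = 65)
  covs <- sim$data$covariates
  covs$site <- factor(rep(c("A", "B", "C"), 100))
  ds <- survival_dataset(sim$data$time, sim$data$status, covs)
  fit <- fit_cox(ds, "x", strata = "site")
  # stratified partial likelihood decomposes over strata
  expect_equal(partial_loglik(ds, "x", fit$coefficients, strata = "site"),
               fit$loglik_fit, tolerance = 1e-8)
  manual <- sum(vapply(c("A", "B", "C"), function(s) {
    i <- covs$site == s
    d <- survival_dataset(ds$time[i], ds$status[i],
                          data.frame(x = covs$x[i]))
    partial_loglik(d, "x", fit$coefficients)
  }, numeric(1)))
  expect_equal(manual, fit$loglik_fit, tolerance = 1e-8)
})
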