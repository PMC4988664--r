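#' Cox proportional-hazards regression
#'
#' Fits the proportional-hazards model
#' `h(t, X) = h0(t) * exp(beta_1 X_1 + ... + beta_q X_q)` by maximizing the
#' partial likelihood under the chosen tie-handling correction (Breslow,
#' Efron, or the exact discrete likelihood).  Categorical covariates are
#' reference-coded against their first level in sorted order.  Optimization
#' is Newton-Raphson from `beta = 0`, declared converged when the relative
#' change in the partial log-likelihood falls below `1e-9` (at most 25
#' iterations).  Per covariate the fit reports the coefficient, its 95%
#' confidence interval, the hazard ratio `exp(beta)` and the Wald-test P
#' value; globally it reports the likelihood-ratio chi-square against the
#' null model and the proportional-hazards assumption diagnostics (scaled
#' Schoenfeld residuals against Kaplan-Meier-transformed time).
#'
#' @param ds A [survival_dataset()].
#' @param covariates Character vector of covariate names to include.
#' @param ties Tie handling: `"efron"` (default), `"breslow"` or `"exact"`.
#' @param strata Optional name of a categorical covariate defining stratified
#'   baseline hazards (separate risk sets per stratum).
#' @param conf_level Confidence level of the coefficient intervals.
#'
#' @return An object of class `cox_fit` with components `coefficients`,
#'   `covariance`, `se`, `hazard_ratios`, `ci` (matrix with columns lower,
#'   upper), `wald_z`, `wald_p`, `loglik_null`, `loglik_fit`, `lrt` (list:
#'   statistic, df, p_value), `ph_test` (see [ph_assumption_test()]),
#'   `ties`, `selected` (covariate names in the model) and the underlying
#'   fitted model object.
#' @examples
#' sim <- generate_cohort(200, rep(0.15, 6), effects = c(x = 0.7), seed = 1)
#' fit_cox(sim$data, "x")
#' @export
fit_cox <- function(ds, covariates, ties = c("efron", "breslow", "exact"),
                    strata = NULL, conf_level = 0.95) {
  stopifnot(inherits(ds, "survival_dataset"))
  ties <- match.arg(ties)
  if (sum(ds$status) < 1L) stop("need at least one event", call. = FALSE)
  miss <- setdiff(c(covariates, strata), names(ds$covariates))
  if (length(miss))
    stop("no covariate named: ", paste(miss, collapse = ", "), call. = FALSE)
  const <- covariates[vapply(covariates, function(v)
    length(unique(ds$covariates[[v]])) < 2L, logical(1))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)

  df <- cox_frame(ds, covariates, strata)
  fml <- cox_formula(covariates, strata, environment())
  fit <- survival::coxph(fml, data = df, ties = ties, model = TRUE,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 25))
  if (any(!is.finite(coef(fit))))
    stop("partial-likelihood maximization failed to converge", call. = FALSE)
  if (any(abs(coef(fit)) > 15))
    warning("very large coefficient(s): the likelihood may be monotone ",
            "(divergent estimate capped by the iteration limit)")
  build_cox_fit(fit, ds, covariates, strata, ties, conf_level)
}

cox_frame <- function(ds, covariates, strata = NULL) {
  df <- cbind(data.frame(.time = ds$time, .status = ds$status),
              ds$covariates[unique(c(covariates, strata))])
  # reference coding against first sorted level
  for (v in covariates)
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  df
}

cox_formula <- function(covariates, strata = NULL, env = parent.frame()) {
  rhs <- paste(c(sprintf("`%s`", covariates),
                 if (!is.null(strata)) sprintf("survival::strata(`%s`)", strata)),
               collapse = " + ")
  stats::as.formula(paste("survival::Surv(.time, .status) ~", rhs), env = env)
}

build_cox_fit <- function(fit, ds, covariates, strata, ties, conf_level) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  wald_z <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(wald_z))
  ll <- fit$loglik
  lrt_stat <- 2 * (ll[2L] - ll[1L])
  lrt <- list(statistic = lrt_stat, df = sum(!is.na(beta)),
              p_value = stats::pchisq(lrt_stat, sum(!is.na(beta)),
                                      lower.tail = FALSE))
  ph <- if (sum(ds$status) >= 2L)
    tryCatch(zph_table(fit), error = function(e) NULL) else NULL
  structure(list(coefficients = beta, covariance = V, se = se,
                 hazard_ratios = exp(beta), ci = ci,
                 wald_z = wald_z, wald_p = wald_p,
                 loglik_null = ll[1L], loglik_fit = ll[2L], lrt = lrt,
                 ph_test = ph, ties = ties, selected = covariates,
                 strata = strata, conf_level = conf_level, fit = fit),
            class = "cox_fit")
}

zph_table <- function(fit) {
  zp <- survival::cox.zph(fit, transform = "km")
  tab <- as.data.frame(zp$table)
  names(tab) <- c("chisq", "df", "p_value")
  tab$term <- rownames(zp$table)
  rownames(tab) <- NULL
  tab[c("term", "chisq", "df", "p_value")]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (ties = ", x$ties,
      if (!is.null(x$strata)) paste0(", strata = ", x$strata), ")\n", sep = "")
  tab <- data.frame(coef = x$coefficients,
                    `exp(coef)` = x$hazard_ratios,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"],
                    p = x$wald_p, check.names = FALSE)
  print(tab, digits = 4)
  cat(sprintf("\nLikelihood-ratio chi-square = %.4g on %d df, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  if (!is.null(x$ph_test)) {
    cat("\nProportional-hazards assumption test:\n")
    print(x$ph_test, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Cox partial log-likelihood at an arbitrary coefficient vector
#'
#' Evaluates the partial log-likelihood of the proportional-hazards model at
#' a given `beta`, under the Breslow, Efron or exact (discrete) tie
#' correction.  Categorical covariates are expanded exactly as in
#' [fit_cox()]; `beta` must match the expanded design columns.  The exact
#' correction computes the tied-risk-set denominator as the elementary
#' symmetric polynomial of the risk weights, i.e. the sum over all subsets of
#' the risk set of the tied-death size.
#'
#' @inheritParams fit_cox
#' @param beta Numeric coefficient vector (length = number of design
#'   columns after categorical expansion).
#' @return The partial log-likelihood (scalar).
#' @examples
#' ds <- survival_dataset(c(1, 2), c(1, 1), data.frame(x = c(1, 0)))
#' partial_loglik(ds, "x", beta = 0.5)  # equals 0.5 - log(exp(0.5) + 1)
#' @export
partial_loglik <- function(ds, covariates, beta,
                           ties = c("efron", "breslow", "exact"),
                           strata = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  ties <- match.arg(ties)
  df <- cox_frame(ds, covariates, strata)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(sprintf("`%s`", covariates),
                                       collapse = " + "))),
    data = df)[, -1L, drop = FALSE]
  if (length(beta) != ncol(X))
    stop("`beta` must have length ", ncol(X),
         " (design columns after categorical expansion)", call. = FALSE)
  eta <- drop(X %*% beta)
  strat <- if (is.null(strata)) rep(1L, nrow(df)) else ds$covariates[[strata]]
  ll <- 0
  for (s in unique(strat)) {
    i <- which(strat == s)
    ll <- ll + partial_loglik_stratum(ds$time[i], ds$status[i], eta[i], ties)
  }
  ll
}

partial_loglik_stratum <- function(time, status, eta, ties) {
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1L]))) {
    risk <- which(time >= t)
    death <- which(time == t & status == 1L)
    d <- length(death)
    ll <- ll + sum(eta[death]) + switch(ties,
      breslow = -d * log(sum(w[risk])),
      efron = {
        wr <- sum(w[risk]); wd <- sum(w[death])
        -sum(log(wr - (seq_len(d) - 1) / d * wd))
      },
      exact = -log(elem_sym(w[risk], d)))
  }
  ll
}

# elementary symmetric polynomial e_d(w) by the stable DP recurrence
elem_sym <- function(w, d) {
  e <- c(1, rep(0, d))
  for (wj in w)
    for (k in seq(min(d, length(e) - 1L), 1L))
      e[k + 1L] <- e[k + 1L] + wj * e[k]
  e[d + 1L]
}

#' Stepwise covariate selection for the Cox model
#'
#' AIC-guided stepwise search over the candidate covariates (backward
#' elimination from the full model, forward selection from the null model, or
#' both directions), then refits the selected subset.
#'
#' @inheritParams fit_cox
#' @param direction `"backward"`, `"forward"` or `"both"`.
#' @return A `cox_fit` for the selected covariates, with an extra component
#'   `trace` (the stepwise ANOVA path) and `selected` naming the retained
#'   covariates (possibly none).
#' @export
stepwise_select <- function(ds, covariates,
                            direction = c("backward", "forward", "both"),
                            ties = c("efron", "breslow", "exact"),
                            strata = NULL, conf_level = 0.95) {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  stopifnot(inherits(ds, "survival_dataset"))
  if (length(covariates) < 2L)
    stop("stepwise selection needs at least 2 candidate covariates",
         call. = FALSE)
  df <- cox_frame(ds, covariates, strata)
  env <- environment()
  full <- cox_formula(covariates, strata, env)
  null <- cox_formula_null(strata, env)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 25)
  start_fml <- if (direction == "forward") null else full
  start <- survival::coxph(start_fml, data = df, ties = ties, control = ctrl,
                           model = TRUE)
  scope <- list(lower = stats::as.formula(paste(
                  "~", if (is.null(strata)) "1"
                       else sprintf("survival::strata(`%s`)", strata)),
                  env = env),
                upper = stats::as.formula(paste(
                  "~", paste(c(sprintf("`%s`", covariates),
                               if (!is.null(strata))
                                 sprintf("survival::strata(`%s`)", strata)),
                             collapse = " + ")), env = env))
  step_dir <- if (direction == "both") "both" else direction
  sel <- MASS::stepAIC(start, scope = scope, direction = step_dir, trace = 0)
  kept <- covariates[vapply(covariates, function(v)
    grepl(sprintf("`%s`", v), deparse1(stats::formula(sel)), fixed = TRUE) ||
      v %in% all.vars(stats::formula(sel)), logical(1))]
  if (length(kept) == 0L) {
    out <- structure(list(coefficients = numeric(0), selected = character(0),
                          ties = ties, strata = strata,
                          loglik_null = sel$loglik[1L],
                          loglik_fit = sel$loglik[length(sel$loglik)],
                          trace = sel$anova, fit = sel),
                     class = "cox_fit")
    return(out)
  }
  out <- fit_cox(ds, kept, ties = ties, strata = strata,
                 conf_level = conf_level)
  out$trace <- sel$anova
  out
}

cox_formula_null <- function(strata = NULL, env = parent.frame()) {
  rhs <- if (is.null(strata)) "1" else sprintf("survival::strata(`%s`)", strata)
  stats::as.formula(paste("survival::Surv(.time, .status) ~", rhs), env = env)
}

#' Proportional-hazards assumption test
#'
#' Grambsch-Therneau test: per covariate, the correlation of the scaled
#' Schoenfeld residuals with the Kaplan-Meier-transformed event-time scale,
#' plus a global chi-square over all covariates.
#'
#' @param fit A `cox_fit` from [fit_cox()].
#' @return Data frame with columns `term`, `chisq`, `df`, `p_value`; the last
#'   row (`GLOBAL`) is the global test.
#' @export
ph_assumption_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (length(fit$coefficients) < 1L)
    stop("the fitted model has no covariates", call. = FALSE)
  if (fit$fit$nevent < 2L)
    stop("the proportional-hazards test needs at least 2 events",
         call. = FALSE)
  zph_table(fit$fit)
}
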