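#' Kaplan-Meier product-limit estimation
#'
#' Estimates the survival function S(t) as the running product of
#' `1 - m_i/n_i` over the distinct observed event times `t_i`, where `m_i` is
#' the number of events at `t_i` and `n_i` the number of subjects at risk just
#' before `t_i`.  Subjects censored at exactly an event time are counted as
#' still at risk there (events precede censorings at tied times).  The 95%
#' confidence band uses the Greenwood variance on the log-survival scale (the
#' convention of the survival package); `conf_type = "plain"` switches to the
#' untransformed symmetric band.
#'
#' @param ds A [survival_dataset()].
#' @param group Optional name of a categorical covariate; one curve is fitted
#'   per level and a named list of class `km_curve_set` is returned.
#' @param conf_level Coverage of the confidence band (default 0.95).
#' @param conf_type `"log"` (log-transformed Greenwood, default) or
#'   `"plain"` (untransformed Greenwood).
#'
#' @return A `km_curve` (or a `km_curve_set` when `group` is given) with
#'   components `time` (distinct event times), `n_risk`, `n_event`, `surv`,
#'   `se` (Greenwood standard error of S), `lower`, `upper`, `median`
#'   (smallest event time with S <= 0.5, `NA` if never reached), `n_total`,
#'   `n_events`, and the observation times used (for risk tables).
#' @examples
#' ds <- survival_dataset(c(1, 2, 3), c(1, 0, 1))
#' fit_km(ds)
#' @export
fit_km <- function(ds, group = NULL, conf_level = 0.95,
                   conf_type = c("log", "plain")) {
  stopifnot(inherits(ds, "survival_dataset"))
  conf_type <- match.arg(conf_type)
  if (is.null(group))
    return(km_single(ds$time, ds$status, conf_level, conf_type))
  if (!group %in% names(ds$covariates))
    stop("no covariate named '", group, "'", call. = FALSE)
  g <- ds$covariates[[group]]
  if (!is.factor(g)) g <- factor(g)
  empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0L]
  if (length(empty))
    stop("group level(s) with no subjects: ", paste(empty, collapse = ", "),
         call. = FALSE)
  out <- lapply(levels(g), function(lv) {
    i <- which(g == lv)
    km_single(ds$time[i], ds$status[i], conf_level, conf_type)
  })
  names(out) <- levels(g)
  structure(out, class = "km_curve_set", group = group)
}

km_single <- function(time, status, conf_level, conf_type) {
  et <- sort(unique(time[status == 1L]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & status == 1L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * sum m / (n (n - m))
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), NA_real_))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "log") {
    se_log <- sqrt(gw)                      # sd of log S
    lower <- surv * exp(-z * se_log)
    upper <- pmin(surv * exp(z * se_log), 1)
  } else {
    lower <- pmax(surv - z * se, 0)
    upper <- pmin(surv + z * se, 1)
  }
  lower[surv == 0] <- NA_real_
  upper[surv == 0] <- NA_real_
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
                 se = se, lower = lower, upper = upper, median = med,
                 n_total = length(time), n_events = sum(status == 1L),
                 conf_level = conf_level, conf_type = conf_type,
                 obs_time = time, obs_status = status),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", x$n_total, ", events = ", x$n_events,
      ", median = ", ifelse(is.na(x$median), "not reached", x$median),
      "\n", sep = "")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
print.km_curve_set <- function(x, ...) {
  cat("<km_curve_set> grouped by '", attr(x, "group"), "' (",
      length(x), " levels)\n", sep = "")
  for (lv in names(x)) { cat("\n$", lv, "\n", sep = ""); print(x[[lv]]) }
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             survival = x$surv, se = x$se, ci_low = x$lower, ci_high = x$upper)
}

#' Median survival time of a fitted Kaplan-Meier curve
#'
#' The smallest event time at which the estimated survival drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return A time, or `NA` if undefined.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median
}

#' Median follow-up time (reverse Kaplan-Meier)
#'
#' Estimates the median of the follow-up (censoring) distribution by applying
#' the Kaplan-Meier estimator with the status indicator flipped, the standard
#' clinical convention.
#'
#' @param ds A [survival_dataset()].
#' @return A time, or `NA` if the flipped curve never reaches 0.5 (e.g. when
#'   no subject is censored).
#' @export
median_followup <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  flipped <- survival_dataset(ds$time, 1L - ds$status, ds$covariates)
  median_survival(fit_km(flipped))
}

#' Number-at-risk table over a time grid
#'
#' Counts, per curve and per grid time, the subjects whose observed follow-up
#' time is at least that grid time — the table printed beneath survival and
#' hazard plots.
#'
#' @param curves A `km_curve`, a `km_curve_set`, or a named list of
#'   `km_curve` objects.
#' @param grid Non-empty, non-decreasing numeric vector of times.
#' @return A data frame with one row per curve and one column per grid time.
#' @export
risk_table <- function(curves, grid) {
  if (length(grid) < 1L || any(diff(grid) < 0))
    stop("`grid` must be non-empty and non-decreasing", call. = FALSE)
  if (inherits(curves, "km_curve")) curves <- list(overall = curves)
  counts <- t(vapply(curves,
                     function(cv) vapply(grid, function(g) sum(cv$obs_time >= g),
                                         numeric(1)),
                     numeric(length(grid))))
  out <- as.data.frame(counts)
  names(out) <- as.character(grid)
  out
}

#' Pointwise confidence band for a Kaplan-Meier curve
#'
#' Recomputes the Greenwood band of a fitted curve at an arbitrary coverage
#' level, on the log-survival scale by default (see [fit_km()]).
#'
#' @param curve A `km_curve`.
#' @param level Coverage in (0, 1).
#' @param conf_type `"log"` or `"plain"`.
#' @return Data frame with columns `time`, `ci_low`, `ci_high`.
#' @export
km_confidence_band <- function(curve, level = 0.95,
                               conf_type = c("log", "plain")) {
  stopifnot(inherits(curve, "km_curve"))
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  conf_type <- match.arg(conf_type)
  refit <- km_single(curve$obs_time, curve$obs_status, level, conf_type)
  data.frame(time = refit$time, ci_low = refit$lower, ci_high = refit$upper)
}
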