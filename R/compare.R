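#' Weighted log-rank comparison of survival curves
#'
#' Compares k >= 2 survival curves with the weighted log-rank family.  At each
#' distinct pooled event time `t_i` the observed events per group are set
#' against the expected events `e_gi = n_gi * m_i / n_i` under the null of a
#' common hazard, weighted by a per-time weight `w_i`:
#' \itemize{
#'   \item log-rank: `w_i = 1`;
#'   \item Peto-Peto: `w_i = S(t_i-)`, the left-continuous pooled
#'     Kaplan-Meier estimate;
#'   \item Tarone-Ware: `w_i = sqrt(n_i)`.
#' }
#' The statistic is the quadratic form of the weighted (O - E) vector in the
#' (generalized) inverse of its hypergeometric covariance, referred to a
#' chi-square distribution with k - 1 degrees of freedom.  For two groups this
#' reduces to the familiar ratio of the squared weighted difference to its
#' summed per-time variance.
#'
#' @param ds A [survival_dataset()].
#' @param group Name of a categorical covariate with k >= 2 levels.
#' @param scheme Weighting scheme: `"log-rank"`, `"peto-peto"` or
#'   `"tarone-ware"`.
#'
#' @return An object of class `curve_comparison`: `statistic`, `df`
#'   (k - 1), `p_value`, `scheme`, `per_group` (data frame with level, n,
#'   observed events, expected events — unweighted — plus their weighted
#'   counterparts) and, for k = 2, `odds_ratio` (see [odds_ratio()]).
#' @examples
#' ds <- survival_dataset(c(1, 2, 3, 4), rep(1, 4),
#'                        data.frame(arm = c("X", "X", "Y", "Y")))
#' compare_curves(ds, "arm")
#' @export
compare_curves <- function(ds, group,
                           scheme = c("log-rank", "peto-peto", "tarone-ware")) {
  stopifnot(inherits(ds, "survival_dataset"))
  scheme <- match.arg(scheme)
  if (!group %in% names(ds$covariates))
    stop("no covariate named '", group, "'", call. = FALSE)
  g <- factor(ds$covariates[[group]])
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("`group` must have at least 2 levels", call. = FALSE)
  if (sum(ds$status) == 0L)
    stop("no events observed; the comparison statistic is undefined",
         call. = FALSE)

  time <- ds$time; status <- ds$status
  et <- sort(unique(time[status == 1L]))
  p <- length(et)
  # pooled and per-group risk/event counts at each distinct event time
  n_i <- vapply(et, function(t) sum(time >= t), numeric(1))
  m_i <- vapply(et, function(t) sum(time == t & status == 1L), numeric(1))
  n_gi <- vapply(levels(g), function(lv)
    vapply(et, function(t) sum(time >= t & g == lv), numeric(1)),
    numeric(p))
  m_gi <- vapply(levels(g), function(lv)
    vapply(et, function(t) sum(time == t & status == 1L & g == lv), numeric(1)),
    numeric(p))
  n_gi <- matrix(n_gi, nrow = p); m_gi <- matrix(m_gi, nrow = p)

  w <- switch(scheme,
    "log-rank"    = rep(1, p),
    "tarone-ware" = sqrt(n_i),
    "peto-peto"   = {                      # left-continuous pooled KM at t_i
      s <- cumprod(1 - m_i / n_i)
      c(1, s[-p])
    })

  e_gi <- n_gi * (m_i / n_i)               # expected events per group/time
  d <- colSums(w * (m_gi - e_gi))          # weighted O - E per group
  # hypergeometric covariance, summed over times with weight w^2
  V <- matrix(0, k, k)
  fac <- ifelse(n_i > 1, m_i * (n_i - m_i) / (n_i^2 * (n_i - 1)), 0)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    vab <- if (a == b) fac * n_gi[, a] * (n_i - n_gi[, a])
           else        -fac * n_gi[, a] * n_gi[, b]
    V[a, b] <- sum(w^2 * vab)
  }
  sub <- seq_len(k - 1L)
  Vs <- V[sub, sub, drop = FALSE]
  stat <- tryCatch(
    drop(t(d[sub]) %*% solve(Vs, d[sub])),
    error = function(e) drop(t(d[sub]) %*% MASS::ginv(Vs) %*% d[sub]))
  pval <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)

  per_group <- data.frame(
    level = levels(g),
    n = as.integer(table(g)),
    events = colSums(m_gi),
    expected = colSums(e_gi),
    observed_weighted = colSums(w * m_gi),
    expected_weighted = colSums(w * e_gi),
    row.names = NULL)

  or <- if (k == 2L) {
    oe <- per_group$events / per_group$expected
    if (any(per_group$expected == 0)) NA_real_ else oe[1L] / oe[2L]
  } else NULL

  structure(list(statistic = stat, df = k - 1L, p_value = pval,
                 scheme = scheme, per_group = per_group, odds_ratio = or),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("Survival curve comparison (", x$scheme, ")\n", sep = "")
  print(x$per_group[c("level", "n", "events", "expected")], digits = 4,
        row.names = FALSE)
  cat(sprintf("\nChisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$odds_ratio))
    cat(sprintf("Odds ratio (O/E vs O/E): %.4g\n", x$odds_ratio))
  invisible(x)
}

#' Odds ratio from a two-group curve comparison
#'
#' The ratio of relative event rates `(O_X / E_X) / (O_Y / E_Y)` built from
#' the (unweighted) observed and expected event counts of the two groups, in
#' the order of the factor levels.  Undefined (`NA`) when a group has zero
#' expected events.
#'
#' @param result A `curve_comparison` from [compare_curves()] with exactly
#'   two groups.
#' @return A positive number, or `NA` when undefined.
#' @export
odds_ratio <- function(result) {
  stopifnot(inherits(result, "curve_comparison"))
  if (is.null(result$odds_ratio))
    stop("odds ratio is only defined when comparing exactly two curves",
         call. = FALSE)
  result$odds_ratio
}
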