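#' Nelson-Aalen cumulative-hazard increments
#'
#' Increments `m_i / n_i` of the Nelson-Aalen estimator at each distinct
#' observed event time, with the running cumulative hazard.
#'
#' @param ds A [survival_dataset()].
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `increment`
#'   (`m_i/n_i`) and `cumhaz`.
#' @examples
#' nelson_aalen(survival_dataset(c(1, 2, 3), c(1, 0, 1)))
#' @export
nelson_aalen <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (sum(ds$status) == 0L)
    stop("no events observed; the Nelson-Aalen estimator is undefined",
         call. = FALSE)
  time <- ds$time; status <- ds$status
  et <- sort(unique(time[status == 1L]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & status == 1L), numeric(1))
  inc <- n_event / n_risk
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             increment = inc, cumhaz = cumsum(inc))
}

#' Epanechnikov kernel
#'
#' The parabola `(3/4)(1 - x^2)` on `[-1, 1]`, zero outside.
#'
#' @param x Numeric vector.
#' @return Kernel values.
#' @export
epanechnikov <- function(x) {
  ifelse(abs(x) <= 1, 0.75 * (1 - x^2), 0)
}

#' Gasser-Mueller boundary kernel of Epanechnikov order
#'
#' Second-order asymmetric kernel on the truncated support `[-1, q]` used
#' near the edges of the data range, constructed as `K(x)(alpha + beta x)`
#' with `alpha`, `beta` chosen so that the kernel integrates to 1 and has
#' vanishing first moment on `[-1, q]`.  At `q = 1` it reduces to the plain
#' Epanechnikov kernel.  The right boundary is handled by reflection
#' (`x -> -x`).
#'
#' @param x Numeric vector of evaluation points.
#' @param q Relative boundary position in [0, 1].
#' @return Kernel values (zero outside `[-1, q]`).
#' @export
boundary_kernel <- function(x, q) {
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]", call. = FALSE)
  # truncated Epanechnikov moments mu_j = int_{-1}^{q} x^j K(x) dx
  mu0 <- 0.75 * (q - q^3 / 3) + 0.5
  mu1 <- 0.75 * (q^2 / 2 - q^4 / 4) - 3 / 16
  mu2 <- 0.75 * (q^3 / 3 - q^5 / 5) + 0.1
  den <- mu0 * mu2 - mu1^2
  alpha <- mu2 / den
  beta <- -mu1 / den
  ifelse(x >= -1 & x <= q, epanechnikov(x) * (alpha + beta * x), 0)
}

#' Kernel-smoothed hazard-rate estimate
#'
#' Fixed-bandwidth kernel smoothing of the Nelson-Aalen increments:
#' `h(t) = (1/b) * sum_i K((t - t_i)/b) * dH(t_i)`, with the Epanechnikov
#' kernel in the interior and Gasser-Mueller boundary kernels within one
#' bandwidth of 0 and of the upper end `t_D` (the largest observed event
#' time).  An optional pointwise band uses the asymptotic variance
#' `(1/b^2) * sum_i K^2((t - t_i)/b) * m_i / (n_i (n_i - m_i))` with normal
#' quantiles.
#'
#' @param ds A [survival_dataset()].
#' @param bandwidth Positive smoothing bandwidth `b`, in time units.
#' @param grid Optional evaluation times within `[0, t_D]`; default
#'   `n_grid` equally spaced points on `[0, t_D]`.
#' @param n_grid Number of default grid points (default 101).
#' @param conf_level Coverage for the optional band; `NULL` (default) skips it.
#'
#' @return An object of class `hazard_curve`: `grid`, `values` (events per
#'   time unit), `bandwidth`, `ci_low`/`ci_high` (or `NULL`), `max_value` and
#'   `max_time` (the curve maximum and where it is attained), `t_max`.
#' @examples
#' ds <- survival_dataset(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 1))
#' smooth_hazard(ds, bandwidth = 2)
#' @export
smooth_hazard <- function(ds, bandwidth, grid = NULL, n_grid = 101L,
                          conf_level = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  na <- nelson_aalen(ds)
  t_d <- max(na$time)
  if (is.null(grid)) grid <- seq(0, t_d, length.out = n_grid)
  if (any(grid < 0 | grid > t_d))
    stop("`grid` must lie within [0, ", t_d, "]", call. = FALSE)
  b <- bandwidth

  kern_at <- function(t) {
    x <- (t - na$time) / b
    if (t < b && t_d - t < b) {
      # bandwidth spans the whole axis: left correction dominates near 0,
      # right correction near t_d; blend by proximity
      if (t <= t_d - t) boundary_kernel(x, t / b)
      else boundary_kernel(-x, (t_d - t) / b)
    } else if (t < b) {
      boundary_kernel(x, t / b)
    } else if (t_d - t < b) {
      boundary_kernel(-x, (t_d - t) / b)
    } else {
      epanechnikov(x)
    }
  }

  values <- vapply(grid, function(t) sum(kern_at(t) * na$increment) / b,
                   numeric(1))
  # boundary kernels have a negative lobe; clip the rare negative estimates
  values <- pmax(values, 0)
  if (all(values == 0))
    warning("bandwidth so small that no event falls within one bandwidth ",
            "of any grid point; the smoothed curve is identically zero")

  ci_low <- ci_high <- NULL
  if (!is.null(conf_level)) {
    vfac <- ifelse(na$n_risk > na$n_event,
                   na$n_event / (na$n_risk * (na$n_risk - na$n_event)), 0)
    v <- vapply(grid, function(t) sum(kern_at(t)^2 * vfac) / b^2, numeric(1))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_low <- pmax(values - z * sqrt(v), 0)
    ci_high <- values + z * sqrt(v)
  }

  imax <- which.max(values)
  structure(list(grid = grid, values = values, bandwidth = b,
                 ci_low = ci_low, ci_high = ci_high,
                 max_value = values[imax], max_time = grid[imax],
                 t_max = t_d, conf_level = conf_level),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("<hazard_curve> bandwidth = ", x$bandwidth, ", ",
      length(x$grid), " grid points on [0, ", x$t_max, "]\n",
      sprintf("maximum hazard %.4g at t = %.4g\n", x$max_value, x$max_time),
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.hazard_curve <- function(x, ...) {
  out <- data.frame(time = x$grid, hazard = x$values)
  if (!is.null(x$ci_low)) { out$ci_low <- x$ci_low; out$ci_high <- x$ci_high }
  out
}
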