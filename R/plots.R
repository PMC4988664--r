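#' Plot Kaplan-Meier curves
#'
#' Step plot of one or several survival curves, optionally with the
#' confidence band, censoring marks and a number-at-risk table beneath.
#' With `bw = TRUE` groups are distinguished by line type only.
#'
#' @param x A `km_curve` or `km_curve_set`.
#' @param ci Draw the confidence band?
#' @param risk_grid Optional time grid; when given, a number-at-risk table is
#'   printed beneath the plot.
#' @param bw Black-and-white graphics (line types instead of colours)?
#' @param xlab,ylab,main Usual graphical annotations.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.km_curve <- function(x, ci = FALSE, risk_grid = NULL, bw = FALSE,
                          xlab = "Time", ylab = "Survival probability",
                          main = NULL, ...) {
  plot_km_curves(list(overall = x), ci = ci, risk_grid = risk_grid, bw = bw,
                 xlab = xlab, ylab = ylab, main = main,
                 legend = FALSE, ...)
  invisible(x)
}

#' @rdname plot.km_curve
#' @export
plot.km_curve_set <- function(x, ci = FALSE, risk_grid = NULL, bw = FALSE,
                              xlab = "Time", ylab = "Survival probability",
                              main = NULL, ...) {
  plot_km_curves(x, ci = ci, risk_grid = risk_grid, bw = bw, xlab = xlab,
                 ylab = ylab, main = main, legend = TRUE, ...)
  invisible(x)
}

km_steps <- function(cv) {
  # step coordinates from S = 1 at t = 0
  tmax <- max(cv$obs_time)
  t <- c(0, rep(cv$time, each = 2), tmax)
  s <- c(1, 1, rep(cv$surv, each = 2))
  list(t = t[seq_along(s)], s = s)
}

plot_km_curves <- function(curves, ci, risk_grid, bw, xlab, ylab, main,
                           legend, ...) {
  k <- length(curves)
  cols <- if (bw) rep(1, k) else seq_len(k)
  ltys <- if (bw) seq_len(k) else rep(1, k)
  tmax <- max(vapply(curves, function(cv) max(cv$obs_time), numeric(1)))
  has_risk <- !is.null(risk_grid)
  if (has_risk) {
    opar <- graphics::par(no.readonly = TRUE)
    on.exit(graphics::par(opar))
    graphics::layout(matrix(1:2), heights = c(4, 1 + 0.35 * k))
    graphics::par(mar = c(4, 4, 2, 1))
  }
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  for (i in seq_len(k)) {
    cv <- curves[[i]]
    st <- km_steps(cv)
    graphics::lines(st$t, st$s, type = "s", col = cols[i], lty = ltys[i])
    cens <- cv$obs_time[cv$obs_status == 0L]
    if (length(cens)) {
      sc <- vapply(cens, function(tc) {
        i0 <- which(cv$time <= tc)
        if (length(i0)) cv$surv[max(i0)] else 1
      }, numeric(1))
      graphics::points(cens, sc, pch = 3, col = cols[i], cex = 0.7)
    }
    if (ci && length(cv$time)) {
      graphics::lines(cv$time, cv$lower, type = "s", lty = 3, col = cols[i])
      graphics::lines(cv$time, cv$upper, type = "s", lty = 3, col = cols[i])
    }
  }
  if (legend && k > 1)
    graphics::legend("bottomleft", legend = names(curves), col = cols,
                     lty = ltys, bty = "n")
  if (has_risk) {
    rt <- risk_table(curves, risk_grid)
    graphics::par(mar = c(1, 4, 0, 1))
    graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, k + 1), axes = FALSE,
                   xlab = "", ylab = "")
    graphics::mtext("At risk", side = 2, las = 1, cex = 0.8)
    for (i in seq_len(k)) {
      graphics::text(0, k + 1 - i, names(curves)[i], adj = 0, cex = 0.8,
                     font = 2)
      graphics::text(risk_grid, k + 1 - i - 0.45, unlist(rt[i, ]), cex = 0.8)
    }
  }
  invisible(NULL)
}

#' Plot smoothed hazard curves
#'
#' One or several kernel-smoothed hazard curves on a common axis, each
#' annotated with its maximum and the time it is reached.
#'
#' @param x A `hazard_curve`, or a named list of them.
#' @param bw Black-and-white graphics?
#' @param annotate_max Mark the curve maximum?
#' @param xlab,ylab,main Usual graphical annotations.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.hazard_curve <- function(x, bw = FALSE, annotate_max = TRUE,
                              xlab = "Time", ylab = "Hazard rate",
                              main = NULL, ...) {
  plot_hazard_curves(list(overall = x), bw = bw, annotate_max = annotate_max,
                     xlab = xlab, ylab = ylab, main = main, legend = FALSE,
                     ...)
  invisible(x)
}

#' @rdname plot.hazard_curve
#' @param curves Named list of `hazard_curve` objects.
#' @export
plot_hazard_curves <- function(curves, bw = FALSE, annotate_max = TRUE,
                               xlab = "Time", ylab = "Hazard rate",
                               main = NULL, legend = TRUE, ...) {
  k <- length(curves)
  cols <- if (bw) rep(1, k) else seq_len(k)
  ltys <- if (bw) seq_len(k) else rep(1, k)
  xmax <- max(vapply(curves, function(cv) max(cv$grid), numeric(1)))
  ymax <- max(vapply(curves, function(cv)
    max(cv$values, cv$ci_high %||% 0), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax * 1.1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  for (i in seq_len(k)) {
    cv <- curves[[i]]
    graphics::lines(cv$grid, cv$values, col = cols[i], lty = ltys[i])
    if (!is.null(cv$ci_low)) {
      graphics::lines(cv$grid, cv$ci_low, col = cols[i], lty = 3)
      graphics::lines(cv$grid, cv$ci_high, col = cols[i], lty = 3)
    }
    if (annotate_max) {
      graphics::points(cv$max_time, cv$max_value, pch = 19, col = cols[i])
      graphics::text(cv$max_time, cv$max_value,
                     sprintf("max %.3g @ %.3g", cv$max_value, cv$max_time),
                     pos = 4, cex = 0.7, col = cols[i])
    }
  }
  if (legend && k > 1)
    graphics::legend("topright", legend = names(curves), col = cols,
                     lty = ltys, bty = "n")
  invisible(curves)
}

#' Plot an individual prediction against the observed discrete curve
#'
#' Step plot comparing the discrete-time survival curve reconstructed from a
#' subject's own encoded targets (the "actual" curve, dotted) with the
#' network prediction (solid), on the interval-index axis.
#'
#' @param x A `survival_prediction`.
#' @param actual_hazards Optional per-interval target vector of the subject
#'   (from [encode_targets()]); when supplied the actual curve is overlaid.
#' @param bw Black-and-white graphics?
#' @param xlab,ylab,main Usual graphical annotations.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.survival_prediction <- function(x, actual_hazards = NULL, bw = FALSE,
                                     xlab = "Follow-up interval",
                                     ylab = "Survival probability",
                                     main = NULL, ...) {
  G <- length(x$hazards)
  graphics::plot(seq_len(G), x$survival, type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main,
                 col = if (bw) 1 else 2, ...)
  if (!is.null(actual_hazards)) {
    graphics::lines(seq_len(G), survival_from_hazards(actual_hazards),
                    type = "s", lty = 3)
    graphics::legend("bottomleft", legend = c("predicted", "actual"),
                     lty = c(1, 3), col = c(if (bw) 1 else 2, 1), bty = "n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
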