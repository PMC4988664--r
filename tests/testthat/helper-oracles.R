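# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity from its defining formula by direct enumeration,
# sharing no code with the package implementation.

# direct product-limit: S(t) = prod over event times u <= t of (1 - m_u/n_u)
km_brute <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  surv <- vapply(et, function(t) {
    prod(vapply(et[et <= t], function(u) {
      1 - sum(time == u & status == 1) / sum(time >= u)
    }, numeric(1)))
  }, numeric(1))
  list(time = et, surv = surv)
}

# Cox partial log-likelihood by direct tie-sum formulas; x a design matrix
cox_loglik_brute <- function(time, status, x, beta, ties) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  total <- 0
  for (t in sort(unique(time[status == 1]))) {
    risk <- which(time >= t)
    dead <- which(time == t & status == 1)
    d <- length(dead)
    num <- sum(eta[dead])
    den <- if (ties == "breslow") {
      d * log(sum(w[risk]))
    } else if (ties == "efron") {
      sum(vapply(seq_len(d), function(l) {
        log(sum(w[risk]) - (l - 1) / d * sum(w[dead]))
      }, numeric(1)))
    } else {  # exact: enumerate all size-d subsets of the risk set
      subsets <- utils::combn(length(risk), d)
      log(sum(apply(subsets, 2, function(s) prod(w[risk[s]]))))
    }
    total <- total + num - den
  }
  total
}

# analytic Efron score (gradient of the partial log-likelihood)
cox_score_efron <- function(time, status, x, beta) {
  x <- as.matrix(x)
  w <- exp(drop(x %*% beta))
  g <- numeric(ncol(x))
  for (t in sort(unique(time[status == 1]))) {
    risk <- which(time >= t)
    dead <- which(time == t & status == 1)
    d <- length(dead)
    sw_r <- sum(w[risk]); sw_d <- sum(w[dead])
    sx_r <- colSums(w[risk] * x[risk, , drop = FALSE])
    sx_d <- colSums(w[dead] * x[dead, , drop = FALSE])
    g <- g + colSums(x[dead, , drop = FALSE])
    for (l in seq_len(d)) {
      a <- (l - 1) / d
      g <- g - (sx_r - a * sx_d) / (sw_r - a * sw_d)
    }
  }
  g
}

# two-sided Fisher p by hypergeometric enumeration over the admissible tables
fisher_brute <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-arm cohort drawn from one (or two) discrete hazard vectors
make_two_arm <- function(n_per_arm, hazards_x, hazards_y = hazards_x,
                         censor_prob = 0, seed = 1) {
  a <- generate_cohort(n_per_arm, hazards_x, censor_prob = censor_prob,
                       seed = seed)
  b <- generate_cohort(n_per_arm, hazards_y, censor_prob = censor_prob,
                       seed = seed + 10000L)
  survival_dataset(c(a$data$time, b$data$time),
                   c(a$data$status, b$data$status),
                   data.frame(arm = rep(c("X", "Y"), each = n_per_arm)))
}
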