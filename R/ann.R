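#' Discretize follow-up time into intervals with equal event counts
#'
#' Splits the follow-up axis `[0, T]` (T = maximum observed follow-up time)
#' into `G` intervals whose boundaries sit at event-time quantiles, so that
#' each interval holds the same number of observed events (+/- 1, with any
#' remainder assigned to the earliest intervals).  Tied event times are never
#' split across a boundary; when heavy ties make an equal split impossible
#' the nearest achievable split is returned with a warning.  Because events
#' typically concentrate early in follow-up, early intervals come out shorter
#' than late ones.
#'
#' @param ds A [survival_dataset()].
#' @param G Number of intervals (>= 2); must not exceed the number of events.
#' @return An object of class `interval_scheme`: `G`, `boundaries` (G + 1
#'   times, first 0, last T), `events_per_interval`, `t_max`.
#' @examples
#' sim <- generate_cohort(200, rep(0.2, 6), seed = 1)
#' discretize(sim$data, 3)
#' @export
discretize <- function(ds, G) {
  stopifnot(inherits(ds, "survival_dataset"))
  G <- as.integer(G)
  if (G < 2L) stop("`G` must be >= 2", call. = FALSE)
  ev <- ds$time[ds$status == 1L]
  M <- length(ev)
  if (M < G)
    stop("fewer events (", M, ") than intervals (", G, ")", call. = FALSE)
  t_max <- max(ds$time)
  dt <- sort(unique(ev))
  if (length(dt) < G)
    stop("only ", length(dt), " distinct event time(s); cannot form ", G,
         " intervals with distinct boundaries", call. = FALSE)
  cnt <- vapply(dt, function(t) sum(ev == t), numeric(1))
  cum <- cumsum(cnt)
  # target counts: floor(M/G) each, remainder + 1 to the earliest intervals
  base <- M %/% G; rem <- M %% G
  target <- base + as.integer(seq_len(G) <= rem)
  tcum <- cumsum(target)[-G]
  # greedy cuts at distinct-time indices nearest the target quantiles,
  # strictly increasing, leaving one distinct time per remaining interval
  cut_idx <- integer(G - 1L)
  prev <- 0L
  nd <- length(dt)
  for (k in seq_len(G - 1L)) {
    lo <- prev + 1L
    hi <- nd - (G - k)
    j <- lo + which.min(abs(cum[lo:hi] - tcum[k])) - 1L
    cut_idx[k] <- j
    prev <- j
  }
  boundaries <- c(0, dt[cut_idx], t_max)
  counts <- diff(c(0, cum[cut_idx], M))
  if (max(counts) - min(counts) > 1L)
    warning("tied event times prevent an equal split; nearest achievable ",
            "counts: ", paste(counts, collapse = ", "))
  structure(list(G = G, boundaries = boundaries,
                 events_per_interval = as.integer(counts), t_max = t_max),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat("<interval_scheme> G = ", x$G, ", boundaries: ",
      paste(signif(x$boundaries, 5), collapse = ", "),
      "\nevents per interval: ", paste(x$events_per_interval, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Interval index of observation times under a scheme
#'
#' Maps times to interval indices 1..G; interval `t` is
#' `(boundaries[t], boundaries[t+1]]` and a time of exactly 0 maps to
#' interval 1.
#'
#' @param scheme An `interval_scheme`.
#' @param time Numeric times in `[0, T]`.
#' @return Integer interval indices.
#' @export
interval_of <- function(scheme, time) {
  stopifnot(inherits(scheme, "interval_scheme"))
  if (any(time < 0 | time > scheme$t_max))
    stop("time outside [0, ", scheme$t_max, "]", call. = FALSE)
  idx <- findInterval(time, scheme$boundaries, left.open = TRUE)
  pmax(pmin(idx, scheme$G), 1L)
}

#' Cohort-level discrete interval hazards
#'
#' Empirical discrete hazard `m_t / n_t` per interval: events in the interval
#' over subjects still at risk at its start (subjects leave the risk set
#' after the interval containing their observed time).
#'
#' @param ds A [survival_dataset()].
#' @param scheme An `interval_scheme` fitted on the same cohort.
#' @return Data frame with columns `interval`, `n_risk`, `n_event`, `hazard`.
#' @export
cohort_hazards <- function(ds, scheme) {
  k <- interval_of(scheme, ds$time)
  G <- scheme$G
  n_t <- vapply(seq_len(G), function(t) sum(k >= t), numeric(1))
  m_t <- vapply(seq_len(G), function(t) sum(k == t & ds$status == 1L),
                numeric(1))
  data.frame(interval = seq_len(G), n_risk = n_t, n_event = m_t,
             hazard = ifelse(n_t > 0, m_t / n_t, 0))
}

#' Per-subject hazard-target encoding
#'
#' Builds the length-`G` training target vector of each subject: zero for
#' every interval up to and including the interval of the observed time; for
#' later intervals, 1 if the subject's event was observed, or the cohort
#' interval hazard `m_t / n_t` if the subject was censored.  With
#' `hazard_at_event = TRUE` an uncensored subject instead carries 1 already
#' at the event interval (the common variant of the encoding).
#'
#' @inheritParams cohort_hazards
#' @param hazard_at_event Logical; see Description.
#' @return A list: `targets` (N x G matrix), `interval` (per-subject interval
#'   index of the observed time), `hazards` (the [cohort_hazards()] table).
#' @examples
#' sim <- generate_cohort(100, rep(0.3, 5), seed = 1)
#' sch <- discretize(sim$data, 3)
#' head(encode_targets(sim$data, sch)$targets)
#' @export
encode_targets <- function(ds, scheme, hazard_at_event = FALSE) {
  stopifnot(inherits(ds, "survival_dataset"))
  ch <- cohort_hazards(ds, scheme)
  k <- interval_of(scheme, ds$time)
  G <- scheme$G
  n <- n_subjects(ds)
  targets <- matrix(0, n, G)
  for (i in seq_len(n)) {
    from <- if (ds$status[i] == 1L && hazard_at_event) k[i] else k[i] + 1L
    if (from <= G)
      targets[i, from:G] <- if (ds$status[i] == 1L) 1 else ch$hazard[from:G]
  }
  list(targets = targets, interval = k, hazards = ch)
}

#' Survival curve from per-interval hazards
#'
#' The discrete product-limit reconstruction: survival at interval `t` is the
#' product of `1 - h_i` over all strictly earlier intervals, so the returned
#' vector starts at 1 and is non-increasing.
#'
#' @param hazards Numeric vector of per-interval hazards in [0, 1].
#' @return Numeric vector of the same length: `S(t) = prod_{i < t} (1 - h_i)`.
#' @examples
#' survival_from_hazards(c(0, 0, 1, 0, 0))  # 1 1 1 0 0
#' @export
survival_from_hazards <- function(hazards) {
  if (any(hazards < 0 | hazards > 1))
    stop("hazards must lie in [0, 1]", call. = FALSE)
  c(1, cumprod(1 - hazards))[seq_along(hazards)]
}

#' Discrete-time prediction accuracy
#'
#' `ACC = sum_i (G - |actual_i - estimated_i|) / (G * N)`: 1 for perfect
#' interval agreement, `1/G` when every prediction is maximally wrong.
#'
#' @param estimated,actual Integer interval indices in 1..G, equal length.
#' @param G Interval count.
#' @return The accuracy in `[1/G, 1]`.
#' @examples
#' accuracy(c(2, 1), c(1, 3), G = 4)  # (3 + 2) / 8
#' @export
accuracy <- function(estimated, actual, G) {
  if (length(estimated) != length(actual))
    stop("`estimated` and `actual` must have equal length", call. = FALSE)
  if (any(c(estimated, actual) < 1L) || any(c(estimated, actual) > G))
    stop("interval indices must lie in 1..G", call. = FALSE)
  sum(G - abs(actual - estimated)) / (G * length(actual))
}

#' Train the discrete-time neural-network survival predictor
#'
#' Fits a single-hidden-layer network (logistic activations at the hidden and
#' output layers, sum-of-squares loss, weight decay) mapping covariates to
#' the `G` per-interval hazard targets of [encode_targets()].  Model
#' selection runs 10-fold cross-validation: the subjects are shuffled once
#' under `seed` into 10 equal folds; in iteration i fold i is the test set,
#' fold i+1 (cyclically) the validation set and the remaining 8 folds train
#' the network.  For every candidate hidden-layer size the network is trained
#' with early stopping on the validation loss; the size with the highest mean
#' validation accuracy (see [accuracy()]) is selected, its mean test-fold
#' accuracy is reported as `cv_accuracy`, and the final network is retrained
#' on the full dataset at that size.  Covariates are standardized (mean 0,
#' unit spread, constants fitted on the training folds only).
#'
#' @inheritParams encode_targets
#' @param scheme An `interval_scheme`, or an integer `G` to discretise with
#'   [discretize()].
#' @param covariates Covariate names to use (default: all).  Categorical
#'   covariates are expanded to reference-coded indicators.
#' @param hidden_grid Candidate hidden-layer sizes.
#' @param seed Integer seed governing fold assignment and weight
#'   initialisation; identical seeds give identical results.
#' @param decay Weight-decay penalty passed to the optimizer.
#' @param max_epochs Optimizer iteration budget per network.
#' @param chunk Iterations between validation checks (early-stopping
#'   granularity).
#' @param patience Stop when the validation loss has not improved for this
#'   many iterations.
#' @return An object of class `ann_survival_model`: `scheme`, `hidden_size`,
#'   `w_hidden` ((p+1) x H weight matrix, bias row first), `w_output`
#'   ((H+1) x G), `center`/`scale` (standardization constants),
#'   `cv_accuracy`, `cv_table` (mean validation accuracy per candidate size),
#'   `design` (covariate expansion info), `hazard_at_event`, `seed`.
#' @export
train_ann <- function(ds, scheme, covariates = NULL,
                      hidden_grid = c(2L, 4L, 8L, 12L, 16L, 20L, 24L, 32L),
                      seed = 1L, decay = 1e-3, max_epochs = 500L,
                      chunk = 100L, patience = 200L,
                      hazard_at_event = FALSE) {
  stopifnot(inherits(ds, "survival_dataset"))
  n <- n_subjects(ds)
  if (n < 10L) stop("need at least 10 subjects for 10-fold CV", call. = FALSE)
  if (length(hidden_grid) < 1L)
    stop("`hidden_grid` must not be empty", call. = FALSE)
  if (is.numeric(scheme) && !inherits(scheme, "interval_scheme"))
    scheme <- discretize(ds, scheme)
  if (is.null(covariates)) covariates <- names(ds$covariates)
  if (length(covariates) < 1L)
    stop("no covariates to train on", call. = FALSE)

  design <- build_design(ds$covariates[covariates])
  X <- design$X
  enc <- encode_targets(ds, scheme, hazard_at_event = hazard_at_event)
  Y <- enc$targets
  k_actual <- enc$interval
  G <- scheme$G

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(10L), length.out = n))

  nH <- length(hidden_grid)
  val_acc <- matrix(NA_real_, 10L, nH)
  test_acc <- matrix(NA_real_, 10L, nH)
  for (iter in seq_len(10L)) {
    i_test <- which(folds == iter)
    i_val <- which(folds == (iter %% 10L) + 1L)
    i_train <- setdiff(seq_len(n), c(i_test, i_val))
    std <- standardizer(X[i_train, , drop = FALSE])
    Xtr <- std$apply(X[i_train, , drop = FALSE])
    Xva <- std$apply(X[i_val, , drop = FALSE])
    Xte <- std$apply(X[i_test, , drop = FALSE])
    for (hi in seq_len(nH)) {
      H <- hidden_grid[hi]
      net <- fit_net(Xtr, Y[i_train, , drop = FALSE],
                     Xva, Y[i_val, , drop = FALSE],
                     H, decay, max_epochs, chunk, patience,
                     net_seed(seed, iter, hi))
      pv <- net_forward(net, Xva)
      pt <- net_forward(net, Xte)
      val_acc[iter, hi] <- accuracy(decode_interval(pv, hazard_at_event),
                                    k_actual[i_val], G)
      test_acc[iter, hi] <- accuracy(decode_interval(pt, hazard_at_event),
                                     k_actual[i_test], G)
    }
  }
  mean_val <- colMeans(val_acc)
  best <- which.max(mean_val)   # ties resolve to the smallest size
  cv_accuracy <- mean(test_acc[, best])

  std <- standardizer(X)
  final <- fit_net(std$apply(X), Y, NULL, NULL, hidden_grid[best], decay,
                   max_epochs, chunk, patience, net_seed(seed, 0L, best))

  structure(list(scheme = scheme, hidden_size = as.integer(hidden_grid[best]),
                 w_hidden = final$w_hidden, w_output = final$w_output,
                 center = std$center, scale = std$scale,
                 cv_accuracy = cv_accuracy,
                 cv_table = data.frame(hidden_size = hidden_grid,
                                       mean_val_accuracy = mean_val),
                 design = design$info, covariates = covariates,
                 hazard_at_event = hazard_at_event, decay = decay,
                 seed = as.integer(seed)),
            class = "ann_survival_model")
}

net_seed <- function(seed, iter, hi) {
  (as.integer(seed) %% 100000L) * 1009L + iter * 131L + hi
}

build_design <- function(covs) {
  covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
  X <- stats::model.matrix(~ ., data = covs)[, -1L, drop = FALSE]
  info <- lapply(covs, function(v) if (is.factor(v)) levels(v) else NULL)
  list(X = X, info = list(levels = info, columns = colnames(X)))
}

standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale,
       apply = function(M) sweep(sweep(M, 2L, center), 2L, scale, "/"))
}

# chunked warm-started nnet with early stopping on validation SSE
fit_net <- function(Xtr, Ytr, Xva, Yva, H, decay, max_epochs, chunk,
                    patience, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- ncol(Xtr); G <- ncol(Ytr)
  wts <- NULL
  best_wts <- NULL
  best_val <- Inf
  used <- 0L
  since_best <- 0L
  while (used < max_epochs) {
    it <- min(chunk, max_epochs - used)
    net <- if (is.null(wts))
      nnet::nnet(Xtr, Ytr, size = H, decay = decay, maxit = it,
                 linout = FALSE, trace = FALSE, MaxNWts = 100000L)
    else
      nnet::nnet(Xtr, Ytr, size = H, decay = decay, maxit = it, Wts = wts,
                 linout = FALSE, trace = FALSE, MaxNWts = 100000L)
    wts <- net$wts
    used <- used + it
    if (!all(is.finite(wts)))
      stop("non-finite network weights during training (H = ", H,
           ", decay = ", decay, ")", call. = FALSE)
    if (is.null(Xva)) {                 # no validation set: run full budget
      best_wts <- wts
      if (net$convergence == 0L) break  # optimizer converged early
      next
    }
    W <- unpack_wts(wts, p, H, G)
    val <- sum((plogis_mat(cbind(1, plogis_mat(cbind(1, Xva) %*% W$w_hidden))
                           %*% W$w_output) - Yva)^2)
    if (val < best_val - 1e-10) {
      best_val <- val; best_wts <- wts; since_best <- 0L
    } else {
      since_best <- since_best + it
      if (since_best >= patience) break
    }
    if (net$convergence == 0L) break
  }
  W <- unpack_wts(best_wts, p, H, G)
  list(w_hidden = W$w_hidden, w_output = W$w_output, H = H)
}

# nnet stores weights per unit as (bias, incoming...); repack as matrices
unpack_wts <- function(wts, p, H, G) {
  w1 <- matrix(wts[seq_len(H * (p + 1L))], nrow = p + 1L)
  w2 <- matrix(wts[H * (p + 1L) + seq_len(G * (H + 1L))], nrow = H + 1L)
  list(w_hidden = w1, w_output = w2)
}

plogis_mat <- function(m) 1 / (1 + exp(-m))

net_forward <- function(net, X) {
  z <- plogis_mat(cbind(1, X) %*% net$w_hidden)
  plogis_mat(cbind(1, z) %*% net$w_output)
}

# estimated interval from predicted hazards; the literal encoding places the
# event one interval before the first drop of the cumulative product
decode_interval <- function(hmat, hazard_at_event) {
  G <- ncol(hmat)
  apply(hmat, 1L, function(h) {
    cum <- cumprod(1 - h)
    idx <- which(cum < 0.5)[1L]
    if (is.na(idx)) return(G)
    if (hazard_at_event) idx else max(1L, idx - 1L)
  })
}

#' @export
print.ann_survival_model <- function(x, ...) {
  cat("<ann_survival_model> G = ", x$scheme$G, ", hidden size = ",
      x$hidden_size, ", cv accuracy = ", round(x$cv_accuracy, 4),
      "\ncandidates:\n", sep = "")
  print(x$cv_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict an individual survival curve from a fitted network
#'
#' Runs the forward pass for one subject and reconstructs the survival curve
#' with the discrete product (see [survival_from_hazards()]).  The estimated
#' survival interval is the interval in which the reconstructed survival
#' first drops below 0.5 (`G` if it never does), adjusted by one interval
#' under the literal encoding, whose targets switch on strictly after the
#' event interval.
#'
#' @param model An `ann_survival_model`.
#' @param covariates A named list, named vector or one-row data frame with
#'   the model's covariates.
#' @return An object of class `survival_prediction`: `hazards` (length G),
#'   `survival` (length G, starts at 1, non-increasing),
#'   `estimated_interval`, `boundaries`.
#' @export
predict_survival <- function(model, covariates) {
  stopifnot(inherits(model, "ann_survival_model"))
  if (is.data.frame(covariates)) covariates <- as.list(covariates[1L, , drop = FALSE])
  covariates <- as.list(covariates)
  miss <- setdiff(model$covariates, names(covariates))
  if (length(miss))
    stop("missing covariate value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  row <- data.frame(row.names = 1L)
  for (v in model$covariates) {
    lev <- model$design$levels[[v]]
    row[[v]] <- if (is.null(lev)) as.numeric(covariates[[v]])
                else factor(as.character(covariates[[v]]), levels = lev)
  }
  X <- stats::model.matrix(~ ., data = row)[, -1L, drop = FALSE]
  if (!identical(colnames(X), model$design$columns))
    stop("covariate expansion does not match the model design (",
         paste(model$design$columns, collapse = ", "), ")", call. = FALSE)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  h <- drop(net_forward(model, Xs))
  s <- survival_from_hazards(h)
  est <- decode_interval(matrix(h, nrow = 1L), model$hazard_at_event)
  structure(list(hazards = h, survival = s, estimated_interval = est,
                 boundaries = model$scheme$boundaries),
            class = "survival_prediction")
}

#' @export
print.survival_prediction <- function(x, ...) {
  print(data.frame(interval = seq_along(x$hazards),
                   hazard = round(x$hazards, 4),
                   survival = round(x$survival, 4)), row.names = FALSE)
  cat("estimated survival interval:", x$estimated_interval, "\n")
  invisible(x)
}

#' Serialize a fitted network model to JSON
#'
#' @param model An `ann_survival_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_survival_model"))
  obj <- list(
    version = "disurv-ann-1",
    scheme = list(G = model$scheme$G, boundaries = model$scheme$boundaries,
                  events_per_interval = model$scheme$events_per_interval,
                  t_max = model$scheme$t_max),
    hidden_size = model$hidden_size,
    w_hidden = model$w_hidden, w_output = model$w_output,
    center = as.list(model$center), scale = as.list(model$scale),
    cv_accuracy = model$cv_accuracy,
    cv_table = model$cv_table,
    covariates = model$covariates,
    design = list(levels = model$design$levels,
                  columns = model$design$columns),
    hazard_at_event = model$hazard_at_event,
    decay = model$decay, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized network model
#'
#' @param path Path to a JSON file written by [write_ann_model()].
#' @return An `ann_survival_model`.
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "disurv-ann-1"))
    stop("unrecognised model file version", call. = FALSE)
  scheme <- structure(list(G = as.integer(obj$scheme$G),
                           boundaries = as.numeric(obj$scheme$boundaries),
                           events_per_interval =
                             as.integer(obj$scheme$events_per_interval),
                           t_max = as.numeric(obj$scheme$t_max)),
                      class = "interval_scheme")
  lv <- obj$design$levels
  lv <- lapply(lv, function(x) if (length(x)) as.character(x) else NULL)
  structure(list(scheme = scheme,
                 hidden_size = as.integer(obj$hidden_size),
                 w_hidden = as.matrix(obj$w_hidden),
                 w_output = as.matrix(obj$w_output),
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 cv_accuracy = as.numeric(obj$cv_accuracy),
                 cv_table = as.data.frame(obj$cv_table),
                 design = list(levels = lv,
                               columns = as.character(obj$design$columns)),
                 covariates = as.character(obj$covariates),
                 hazard_at_event = isTRUE(obj$hazard_at_event),
                 decay = as.numeric(obj$decay),
                 seed = as.integer(obj$seed)),
            class = "ann_survival_model")
}
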