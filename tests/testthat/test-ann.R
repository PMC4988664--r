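test_that("discretization balances event counts and orders boundaries", {
  # 40 events at distinct times, G = 8: exactly 5 events per interval
  ds <- survival_dataset(seq_len(40), rep(1L, 40))
  sch <- discretize(ds, 8)
  expect_equal(sch$events_per_interval, rep(5L, 8))
  expect_equal(sch$boundaries[1], 0)
  expect_equal(sch$boundaries[9], 40)
  expect_true(all(diff(sch$boundaries) > 0))

  # early-heavy events: the early intervals are shorter
  early <- survival_dataset(c(1:30 / 10, 20, 40, 60, 80, 100),
                            rep(1L, 35))
  se <- discretize(early, 5)
  w <- diff(se$boundaries)
  expect_lt(w[1], w[5])

  # remainder events land in the earliest intervals
  ds2 <- survival_dataset(seq_len(10), rep(1L, 10))
  s3 <- discretize(ds2, 3)
  expect_equal(s3$events_per_interval, c(4L, 3L, 3L))

  expect_error(discretize(ds2, 1), ">= 2")
  expect_error(discretize(survival_dataset(1:3, c(1, 0, 0)), 2), "fewer events")
  # all events at a single time: no split can exist
  expect_error(discretize(survival_dataset(rep(2, 5), rep(1L, 5)), 2),
               "distinct")
  # heavy ties: nearest achievable split with a warning
  expect_warning(discretize(survival_dataset(c(rep(1, 8), 2, 3),
                                             rep(1L, 10)), 2),
                 "nearest achievable")
})

test_that("interval lookup respects right-closed intervals and the origin", {
  sch <- discretize(survival_dataset(c(1, 2, 3, 4), rep(1L, 4)), 4)
  expect_equal(interval_of(sch, c(0, 0.5, 1, 1.1, 4)), c(1, 1, 1, 2, 4))
  expect_error(interval_of(sch, 5), "outside")
})

test_that("target encoding follows the three branches of the hazard rule", {
  # five equally populated intervals at times 1..5
  ds <- survival_dataset(c(rep(1:5, 2), 5), c(rep(1L, 10), 0L))
  sch <- discretize(ds, 5)
  enc <- encode_targets(ds, sch)
  k <- enc$interval

  # uncensored with event in interval 3: zeros through 3, ones after
  i3 <- which(k == 3 & ds$status == 1L)[1]
  expect_equal(enc$targets[i3, ], c(0, 0, 0, 1, 1))

  # uncensored at the last interval: all zeros (no t exceeds it)
  iG <- which(k == 5 & ds$status == 1L)[1]
  expect_equal(enc$targets[iG, ], rep(0, 5))

  # censored subject carries the cohort hazards after its interval
  cens <- survival_dataset(c(rep(1:5, 2), 2), c(rep(1L, 10), 0L))
  sch2 <- discretize(cens, 5)
  enc2 <- encode_targets(cens, sch2)
  ic <- which(cens$status == 0L)
  expect_equal(enc2$targets[ic, 1:2], c(0, 0))
  expect_equal(enc2$targets[ic, 3:5], enc2$hazards$hazard[3:5])
  expect_true(all(enc2$hazards$hazard >= 0 & enc2$hazards$hazard <= 1))

  # the at-event variant switches the event interval itself to one
  enc3 <- encode_targets(ds, sch, hazard_at_event = TRUE)
  expect_equal(enc3$targets[i3, ], c(0, 0, 1, 1, 1))
})

test_that("the survival product reconstruction matches brute force", {
  expect_equal(survival_from_hazards(c(0, 0, 1, 0, 0)), c(1, 1, 1, 0, 0))
  expect_equal(survival_from_hazards(rep(0, 4)), rep(1, 4))
  set.seed(10)
  for (i in 1:20) {
    h <- runif(sample(3:10, 1))
    s <- survival_from_hazards(h)
    brute <- vapply(seq_along(h), function(t) prod(1 - h[seq_len(t - 1)]),
                    numeric(1))
    expect_equal(s, brute)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
  expect_error(survival_from_hazards(c(0.5, 1.2)), "0, 1")
})

test_that("the accuracy score has its closed forms and stays in [1/G, 1]", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3), G = 5), 1)
  expect_equal(accuracy(rep(1, 4), rep(6, 4), G = 6), 1 / 6)
  expect_equal(accuracy(c(2, 1), c(1, 3), G = 4), 0.625)
  expect_error(accuracy(c(0, 1), c(1, 1), G = 4), "1..G")
  expect_error(accuracy(1, c(1, 2), G = 4), "equal length")

  set.seed(20)
  for (i in 1:25) {
    G <- sample(2:10, 1)
    n <- sample(1:30, 1)
    a <- sample(G, n, replace = TRUE)
    e <- sample(G, n, replace = TRUE)
    acc <- accuracy(e, a, G)
    expect_gte(acc, 1 / G)
    expect_lte(acc, 1)
  }
})

test_that("pushing estimates further from the truth never raises the accuracy", {
  set.seed(30)
  G <- 8
  a <- sample(G, 50, replace = TRUE)
  e <- sample(G, 50, replace = TRUE)
  # shift each estimate one step away from its actual (clamped at the edges)
  worse <- ifelse(e >= a, pmin(e + 1L, G), pmax(e - 1L, 1L))
  expect_lte(accuracy(worse, a, G), accuracy(e, a, G))
})

test_that("a covariate that determines the event interval is learned exactly", {
  # x = 0 dies in interval 1, x = 1 dies in interval 2: separable problem
  ds <- survival_dataset(rep(c(1, 3), each = 40), rep(1L, 80),
                         data.frame(x = rep(c(0, 1), each = 40)))
  sch <- discretize(ds, 2)
  model <- train_ann(ds, sch, hidden_grid = c(2), seed = 4)
  expect_equal(model$cv_accuracy, 1)
  p0 <- predict_survival(model, list(x = 0))
  p1 <- predict_survival(model, list(x = 1))
  expect_equal(p0$estimated_interval, 1L)
  expect_equal(p1$estimated_interval, 2L)
})

test_that("training is bitwise reproducible under a fixed seed", {
  sim <- generate_cohort(200, rep(0.25, 5), effects = c(x = 1), seed = 8)
  m1 <- suppressWarnings(train_ann(sim$data, 3, hidden_grid = c(2, 4),
                                   seed = 12, max_epochs = 200))
  m2 <- suppressWarnings(train_ann(sim$data, 3, hidden_grid = c(2, 4),
                                   seed = 12, max_epochs = 200))
  expect_identical(m1$w_hidden, m2$w_hidden)
  expect_identical(m1$w_output, m2$w_output)
  expect_identical(m1$cv_accuracy, m2$cv_accuracy)
  expect_identical(m1$hidden_size, m2$hidden_size)
})

test_that("models survive a JSON serialization round trip", {
  sim <- generate_cohort(150, rep(0.25, 5), effects = c(x = 0.8, z = -0.5),
                         seed = 18)
  m <- suppressWarnings(train_ann(sim$data, 3, hidden_grid = c(3),
                                  seed = 2, max_epochs = 150))
  f <- withr::local_tempfile(fileext = ".json")
  write_ann_model(m, f)
  m2 <- read_ann_model(f)
  for (pat in list(list(x = 0, z = 0), list(x = 1, z = 0), list(x = 1, z = 1))) {
    a <- predict_survival(m, pat)
    b <- predict_survival(m2, pat)
    expect_equal(a$hazards, b$hazards, tolerance = 1e-12)
    expect_equal(a$estimated_interval, b$estimated_interval)
  }
})

test_that("predictions respect the survival invariants and input contract", {
  sim <- generate_cohort(150, rep(0.25, 5), effects = c(x = 0.8), seed = 28)
  m <- suppressWarnings(train_ann(sim$data, 3, hidden_grid = c(3), seed = 3,
                                  max_epochs = 150))
  p <- predict_survival(m, list(x = 1))
  expect_length(p$hazards, 3)
  expect_true(all(p$hazards > 0 & p$hazards < 1))   # logistic output
  expect_equal(p$survival[1], 1)
  expect_true(all(diff(p$survival) <= 1e-12))
  expect_error(predict_survival(m, list(y = 1)), "missing covariate")
})

test_that("network forward pass matches the nnet reference implementation", {
  set.seed(40)
  x <- matrix(rnorm(60), ncol = 2)
  y <- matrix(runif(90), ncol = 3)
  net <- nnet::nnet(x, y, size = 4, decay = 1e-3, maxit = 50, linout = FALSE,
                    trace = FALSE)
  w1 <- matrix(net$wts[1:(4 * 3)], nrow = 3)
  w2 <- matrix(net$wts[(4 * 3) + 1:(3 * 5)], nrow = 5)
  ours <- 1 / (1 + exp(-(cbind(1, 1 / (1 + exp(-(cbind(1, x) %*% w1)))) %*% w2)))
  expect_equal(unname(ours), unname(predict(net, x)), tolerance = 1e-10)
})
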