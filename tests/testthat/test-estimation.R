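test_that("step 1 recovers the linear model exactly and matches oracles", {
  b <- make_linear_beat(mu = 0.05, eta = 0.8, beta_A = 60)
  est <- estimate_step1(b$bp, b$ppg, b$d1, b$d2)
  expect_lt(abs(est[["mu"]] - 0.05) / 0.05, 1e-9)
  expect_lt(abs(est[["eta"]] - 0.8) / 0.8, 1e-9)
  expect_lt(abs(est[["beta_A"]] - 60) / 60, 1e-9)

  # equals the closed-form normal-equation solution on random instances
  set.seed(31)
  for (k in 1:20) {
    n <- 200
    ppg <- runif(n); d1 <- rnorm(n); d2 <- rnorm(n)
    bp <- 80 + rnorm(n)
    est <- estimate_step1(bp, ppg, d1, d2)
    X <- cbind(d2 - d2[1], d1 - d1[1], ppg - ppg[1])
    ne <- solve(crossprod(X), crossprod(X, bp - bp[1]))
    expect_lt(max(abs(est - as.numeric(ne))), 1e-10)
  }
})

test_that("step-1 least squares beats a brute-force parameter lattice", {
  set.seed(17)
  n <- 50
  ppg <- runif(n); d1 <- rnorm(n); d2 <- rnorm(n)
  truth <- c(0.05, 0.8, 60)
  bp <- 80 + 0.05 * (d2 - d2[1]) + 0.8 * (d1 - d1[1]) + 60 * (ppg - ppg[1]) +
    rnorm(n, sd = 0.3)
  est <- estimate_step1(bp, ppg, d1, d2)
  rss <- function(p) {
    pred <- p[1] * (d2 - d2[1]) + p[2] * (d1 - d1[1]) + p[3] * (ppg - ppg[1])
    sum((bp - bp[1] - pred)^2)
  }
  lattice <- expand.grid(mu = truth[1] * seq(0.9, 1.1, length.out = 9),
                         eta = truth[2] * seq(0.9, 1.1, length.out = 9),
                         beta_A = truth[3] * seq(0.9, 1.1, length.out = 9))
  grid_best <- min(apply(lattice, 1, rss))
  expect_lte(rss(est), grid_best * (1 + 1e-12))
  # and the grid minimizer sits within 1% of the LS solution per coordinate
  best_row <- lattice[which.min(apply(lattice, 1, rss)), ]
  expect_equal(as.numeric(best_row), as.numeric(est), tolerance = 0.03)
})

test_that("flat PPG gives a rank-deficiency error", {
  n <- 100
  expect_error(estimate_step1(rnorm(n, 80), rep(0.5, n), rep(0, n), rep(0, n)),
               class = "artstiff_estimation_error")
})

test_that("step 2 solves the constructed log-linear identity exactly", {
  set.seed(5)
  n <- 200
  ppg <- sort(runif(n, 0, 0.5)); ppg[1] <- 0
  z <- rep(0, n)
  q0 <- 70
  bp <- q0 * exp(2 * (ppg - ppg[1])) # q(t) = q(t0) exp(2 dPl)
  s2 <- estimate_step2(bp, ppg, z, z, mu = 0, eta = 0, min_mask = 10)
  expect_equal(s2$beta, 2, tolerance = 1e-12)
})

test_that("step 2 with true viscoelastic terms recovers beta from model data", {
  b <- make_model_beat(viscoelastic_params(mu = 0.05, eta = 0.8, beta = 2.0,
                                           p_b0 = log(60)))
  s2 <- estimate_step2(b$bp, b$ppg, b$d1, b$d2, mu = 0.05, eta = 0.8)
  expect_lt(abs(s2$beta - 2.0) / 2.0, 1e-6)
  expect_gte(s2$n_masked, 30)
})

test_that("an empty or undersized step-2 mask flags the beat invalid", {
  n <- 100
  ppg <- runif(n); z <- rep(0, n)
  bp <- rep(-5, n)  # q < 0 everywhere: mask empty, reference invalid
  expect_error(estimate_step2(bp, ppg, z, z, mu = 0, eta = 0),
               class = "artstiff_invalid_beat")
})

test_that("noiseless beats are reconstructed near-perfectly", {
  b <- make_model_beat()
  est <- estimate_beat(b$bp, b$ppg, b$d1, b$d2)
  expect_gt(est$r2, 0.999)
  expect_true(est$accepted)
  expect_lt(abs(est$beta - b$params$beta) / b$params$beta, 1e-8)
  expect_lt(abs(est$mu - b$params$mu) / b$params$mu, 1e-8)
  expect_lt(abs(est$eta - b$params$eta) / b$params$eta, 1e-8)
  # the reconstructed exponent offset matches p_b0 + p_bnl_const
  expect_lt(abs(est$intercept - (b$params$p_b0 + b$params$p_bnl_const)), 1e-8)
})

test_that("single-pass estimates carry the documented linearization bias", {
  b <- make_model_beat()
  single <- estimate_beat(b$bp, b$ppg, b$d1, b$d2, refine = FALSE)
  refined <- estimate_beat(b$bp, b$ppg, b$d1, b$d2, refine = TRUE)
  expect_identical(single$iterations, 0L)
  # single-pass beta is biased on exponential data; refinement removes it
  expect_gt(abs(single$beta - b$params$beta) / b$params$beta, 1e-3)
  expect_lt(abs(refined$beta - b$params$beta) / b$params$beta, 1e-8)
  # beta_A is a step-1 quantity, identical in both
  expect_identical(single$beta_A, refined$beta_A)
})

test_that("R^2 follows its definition for a degenerate flat prediction", {
  bp <- c(78, 82, 80, 79, 81)
  pred <- rep(mean(bp), 5)
  r2 <- 1 - sum((bp - pred)^2) / sum((bp - mean(bp))^2)
  expect_equal(r2, 0)
})

test_that("step-1 estimates are exactly invariant to a BP offset", {
  b <- make_model_beat(sigma_bp = 0.5)
  e1 <- estimate_step1(b$bp, b$ppg, b$d1, b$d2)
  e2 <- estimate_step1(b$bp + 25, b$ppg, b$d1, b$d2)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("PPG gain k rescales beta, mu, eta by 1/k", {
  b <- make_model_beat()
  k <- 2.5
  e1 <- estimate_beat(b$bp, b$ppg, b$d1, b$d2)
  e2 <- estimate_beat(b$bp, k * b$ppg, k * b$d1, k * b$d2)
  expect_equal(e2$beta, e1$beta / k, tolerance = 1e-9)
  expect_equal(e2$mu, e1$mu / k, tolerance = 1e-9)
  expect_equal(e2$eta, e1$eta / k, tolerance = 1e-9)
  expect_equal(e2$r2, e1$r2, tolerance = 1e-9)
})

test_that("per-beat errors are isolated, never fatal to the record", {
  synth <- synthesize_record(stim_protocol(levels = 0, rest_s = 4, stim_s = 4,
                                           eval_s = 4), fs = 1000,
                             sigma_bp = 0.2, seed = 8, keep_derivatives = TRUE)
  rec <- synth$record
  beats <- segment_beats(rec)
  # corrupt two beats with NaN blood pressure
  bad <- c(2L, 5L)
  for (k in bad) rec$bp[beats$start_sample[k] + 10] <- NaN
  est <- suppressMessages(
    estimate_record(rec, beats, derivatives = "record"))
  expect_equal(nrow(est), nrow(beats))
  expect_true(all(is.na(est$beta[bad])))
  expect_true(all(!est$accepted[bad]))
  expect_true(all(!is.na(est$note[bad])))
  good <- setdiff(seq_len(nrow(beats)), bad)
  expect_true(all(is.finite(est$beta[good])))
})

test_that("a record with every beat rejected warns instead of failing", {
  synth <- synthesize_record(stim_protocol(levels = 0, rest_s = 3, stim_s = 3,
                                           eval_s = 3), fs = 1000,
                             sigma_bp = 25, seed = 9, keep_derivatives = TRUE)
  expect_warning(
    est <- estimate_record(synth$record, derivatives = "record"),
    "gate")
  expect_true(all(!est$accepted))
})
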