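make_estimates <- function(t0, beta, accepted = TRUE) {
  tibble::tibble(beat = seq_along(t0), t0 = t0, beta = beta,
                 accepted = rep_len(accepted, length(t0)))
}

test_that("beta_n is beta over the accepted baseline maximum", {
  est <- make_estimates(c(1, 2, 3, 20), c(1.8, 2.0, 1.9, 3.0))
  s <- normalize_beta(est, baseline = c(0, 10))
  expect_equal(s$beta_n, c(1.8, 2.0, 1.9, 3.0) / 2.0)
  expect_equal(max(s$beta_n[s$t0 < 10]), 1)
  expect_equal(attr(s, "beta_baseline_max"), 2.0)

  s_flat <- normalize_beta(make_estimates(1:5, rep(2.2, 5)), c(0, 10))
  expect_true(all(s_flat$beta_n == 1))
})

test_that("normalization requires an accepted baseline beat and ignores rejected ones", {
  est <- make_estimates(c(1, 2, 20), c(5, 1.5, 2), accepted = c(FALSE, TRUE, TRUE))
  s <- normalize_beta(est, baseline = c(0, 10))
  expect_equal(attr(s, "beta_baseline_max"), 1.5)  # rejected 5 not used
  expect_error(normalize_beta(est, baseline = c(30, 40)),
               class = "artstiff_normalization_error")
  expect_error(normalize_beta(est, baseline = c(10, 5)),
               class = "artstiff_parameter_error")
})

test_that("beta_n is exactly invariant to rescaling all beta", {
  est <- make_estimates(c(1, 2, 3, 20, 21), c(1.8, 2.0, 1.9, 3.0, 2.4))
  s1 <- normalize_beta(est, c(0, 10))
  est2 <- est; est2$beta <- est$beta * 7.3
  s2 <- normalize_beta(est2, c(0, 10))
  expect_equal(s1$beta_n, s2$beta_n, tolerance = 1e-14)
})

test_that("eNRS follows the piecewise sigmoid definition", {
  expect_equal(enrs(c(0.2, 0.9, 1), a = 2, b = 1), c(0, 0, 0))
  expect_equal(enrs(2, a = 2, b = 1), 20 / (1 + exp(2)))
  expect_equal(enrs(1e9, a = 2, b = 1), 10, tolerance = 1e-6)
  expect_error(enrs(2, a = 0, b = 1), class = "artstiff_parameter_error")
})

test_that("eNRS is monotone and bounded on (0, Inf) for random shapes", {
  set.seed(41)
  grid <- c(seq(0.01, 1, length.out = 50), 1 + 10^seq(-6, 2, length.out = 200))
  ok <- TRUE
  for (k in 1:25) {
    a <- exp(runif(1, log(0.05), log(20)))
    b <- exp(runif(1, log(0.1), log(5)))
    v <- enrs(grid, a, b)
    ok <- ok && all(diff(v) >= 0) && all(v >= 0 & v < 10) &&
      all(v[grid <= 1] == 0)
  }
  expect_true(ok)
})

test_that("stimulus sigmoid hits its limits and closed forms", {
  expect_equal(stimulus_sigmoid(0, a = 1, b = 1), 1)
  expect_equal(stimulus_sigmoid(1, a = 1, b = 1), 10 / (1 + exp(1)) + 1)
  expect_equal(stimulus_sigmoid(1e9, a = 1, b = 1), 6, tolerance = 1e-6)
  s <- stimulus_sigmoid(seq(0, 3, by = 0.05), a = 2, b = 1.5)
  expect_true(all(diff(s) >= 0))       # flat only where exp() overflows
  expect_true(all(diff(s[s > 1]) > 0)) # strictly increasing once representable
})

test_that("sigmoid fits recover their own forward map", {
  x <- c(0, 0.5, 1, 1.5)
  y <- stimulus_sigmoid(x, a = 3, b = 2)
  fit <- fit_sigmoid(x, y, "stimulus")
  expect_lt(abs(fit$a - 3) / 3, 1e-4)
  expect_lt(abs(fit$b - 2) / 2, 1e-4)
  expect_gt(fit$r2, 1 - 1e-8)

  # eNRS variant self-consistency
  xb <- c(1.05, 1.2, 1.5, 2, 3)
  yb <- enrs(xb, a = 2, b = 1.2)
  fitb <- fit_sigmoid(xb, yb, "enrs")
  expect_lt(abs(fitb$a - 2) / 2, 1e-3)
  expect_lt(abs(fitb$b - 1.2) / 1.2, 1e-3)
})

test_that("noisy sigmoid fits recover parameters within tolerance", {
  set.seed(12)
  x <- rep(c(0, 0.5, 1, 1.5), each = 3)
  errs <- replicate(30, {
    y <- stimulus_sigmoid(x, a = 3, b = 2) + rnorm(length(x), sd = 0.2)
    fit <- suppressWarnings(fit_sigmoid(x, y, "stimulus"))
    max(abs(fit$a - 3) / 3, abs(fit$b - 2) / 2)
  })
  expect_lt(median(errs), 0.10)
})

test_that("degenerate sigmoid inputs raise fit errors", {
  expect_error(fit_sigmoid(c(0, 0.5, 1), rep(2, 3), "stimulus"),
               class = "artstiff_fit_error")
  expect_error(fit_sigmoid(c(1, 1, 1), c(1, 2, 3), "stimulus"),
               class = "artstiff_fit_error")
})

test_that("linear fits return slope, intercept, R^2 and significance", {
  fit <- fit_linear(0:4, 2 * (0:4) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_error(fit_linear(rep(1, 5), rnorm(5)), class = "artstiff_fit_error")

  set.seed(13)
  slopes <- replicate(300, {
    x <- 0:6
    fit_linear(x, 1 + 0.5 * x + rnorm(7, sd = 0.4))$slope
  })
  expect_lt(abs(mean(slopes) - 0.5), 3 * sd(slopes) / sqrt(300))
})

test_that("tidy and glance methods expose fit summaries", {
  fit <- fit_sigmoid(c(0, 0.5, 1, 1.5), stimulus_sigmoid(c(0, 0.5, 1, 1.5), 3, 2),
                     "stimulus")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  gl <- glance(fit)
  expect_equal(gl$variant, "stimulus")
  expect_true(gl$r.squared > 0.99)

  lf <- fit_linear(1:5, 2 * (1:5) + rnorm(5, sd = 0.01))
  expect_equal(nrow(tidy(lf)), 2)
  expect_true(all(c("r.squared", "p.value", "nobs") %in% names(glance(lf))))
})

test_that("trial summaries average beta_n inside stimulation windows", {
  proto <- stim_protocol(levels = c(0, 1), rest_s = 2, stim_s = 4, eval_s = 2)
  est <- make_estimates(c(2.5, 3.5, 10.5, 11.5), c(2, 2, 3, 5))
  s <- normalize_beta(est, baseline = c(2, 6))
  trl <- summarize_trials(s, proto)
  expect_equal(trl$n_beats, c(2L, 2L))
  expect_equal(trl$mean_beta_n, c(1, mean(c(3, 5)) / 2))
})
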