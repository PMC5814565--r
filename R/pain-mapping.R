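#' Normalize the stiffness index against a no-stimulation baseline
#'
#' Divides every accepted beat's stiffness index by the maximum accepted
#' `beta` inside the baseline (no-stimulation) window, giving the normalized
#' index `beta_n` -- the change rate of `beta` relative to rest. By
#' construction the maximum of `beta_n` over the baseline window equals 1
#' exactly, and `beta_n` is invariant to rescaling all `beta` by a positive
#' constant.
#'
#' @param estimates A `beat_estimates` tibble from [estimate_record()];
#'   rejected beats are dropped.
#' @param baseline Numeric `c(start, end)` in seconds: the no-stimulation
#'   window (half-open, on beat reference times t0).
#' @return A `stiffness_series` tibble with columns `beat`, `t0`, `beta`,
#'   `beta_n`, and attributes `baseline` and `beta_baseline_max`.
#' @examples
#' est <- tibble::tibble(beat = 1:4, t0 = c(1, 2, 11, 12),
#'                       beta = c(1.8, 2.0, 1.9, 3.0),
#'                       accepted = TRUE)
#' normalize_beta(est, baseline = c(0, 10))
#' @export
normalize_beta <- function(estimates, baseline) {
  if (length(baseline) != 2 || baseline[1] >= baseline[2])
    abort("`baseline` must be c(start, end) with start < end.",
          class = "artstiff_parameter_error")
  acc <- dplyr::filter(tibble::as_tibble(estimates),
                       .data$accepted, is.finite(.data$beta))
  base <- dplyr::filter(acc, .data$t0 >= baseline[1], .data$t0 < baseline[2])
  if (nrow(base) == 0)
    abort("no accepted beat inside the baseline window.",
          class = "artstiff_normalization_error")
  ref <- max(base$beta)
  out <- dplyr::transmute(acc, beat = .data$beat, t0 = .data$t0,
                          beta = .data$beta, beta_n = .data$beta / ref)
  attr(out, "baseline") <- c(start = baseline[1], end = baseline[2])
  attr(out, "beta_baseline_max") <- ref
  class(out) <- c("stiffness_series", class(out))
  out
}

#' Estimated numeric pain rating from normalized stiffness
#'
#' Converts the normalized stiffness index `beta_n` to an estimated numeric
#' rating scale score through the bounded piecewise sigmoid
#' \deqn{eNRS = 20 / (1 + \exp(a (\beta_n - 1)^{-b})) \quad (\beta_n > 1);
#'       \qquad 0 \quad (\beta_n \le 1),}
#' which is 0 for any stiffness at or below rest, continuous from the right
#' at `beta_n = 1`, strictly increasing above it, and bounded below 10.
#'
#' @param beta_n Normalized stiffness values.
#' @param a,b Sigmoid shape parameters (> 0), or supply `map`.
#' @param map Optionally a fitted [fit_sigmoid()] object of variant
#'   `"enrs"`, whose `a` and `b` are used.
#' @return eNRS values in `[0, 10)`.
#' @examples
#' enrs(c(0.9, 1.5, 3), a = 2, b = 1)
#' @export
enrs <- function(beta_n, a = NULL, b = NULL, map = NULL) {
  if (!is.null(map)) {
    stopifnot(inherits(map, "sigmoid_map"))
    if (map$variant != "enrs")
      abort("`map` must be an `enrs`-variant sigmoid.",
            class = "artstiff_parameter_error")
    a <- map$a; b <- map$b
  }
  if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
    abort("`a` and `b` must be strictly positive.",
          class = "artstiff_parameter_error")
  out <- numeric(length(beta_n))
  up <- which(beta_n > 1)
  out[up] <- 20 / (1 + exp(a * (beta_n[up] - 1)^(-b)))
  out
}

#' Stimulus-response sigmoid
#'
#' The bounded sigmoid relating stimulus level `S` (in multiples of the
#' standard current amplitude) to a response on a 1-6 scale:
#' `10 / (1 + exp(a * S^-b)) + 1`. The expression is undefined at `S = 0`
#' (the exponent diverges); the value there is defined by the limit, 1, so
#' zero-level trials are usable. Strictly increasing in `S` for `a, b > 0`,
#' saturating at 6.
#'
#' @param S Stimulus level(s), >= 0.
#' @param a,b Shape parameters (> 0).
#' @return Response values in `[1, 6)`.
#' @examples
#' stimulus_sigmoid(c(0, 0.5, 1, 1.5), a = 3, b = 2)
#' @export
stimulus_sigmoid <- function(S, a, b) {
  if (a <= 0 || b <= 0)
    abort("`a` and `b` must be strictly positive.",
          class = "artstiff_parameter_error")
  if (any(S < 0))
    abort("`S` must be non-negative.", class = "artstiff_parameter_error")
  out <- rep(1, length(S))
  pos <- which(S > 0)
  out[pos] <- 10 / (1 + exp(pmin(a * S[pos]^(-b), 700))) + 1
  out
}

# evaluate a variant's sigmoid at x for given (a, b)
sigmoid_eval <- function(x, a, b, variant) {
  if (variant == "stimulus") return(stimulus_sigmoid(x, a, b))
  enrs(x, a, b)
}

#' Fit a bounded sigmoid map by multi-start nonlinear least squares
#'
#' Fits the shape parameters `(a, b)` of either sigmoid family -- the
#' stimulus-response variant (`x` = stimulus level, response in `[1, 6)`) or
#' the eNRS variant (`x` = normalized stiffness, response in `[0, 10)`) --
#' by nonlinear least squares. The parameters are optimized on the log scale
#' (enforcing `a, b > 0`) from a deterministic grid of log-spaced starting
#' points, and the best converged fit is polished and returned with
#' diagnostics.
#'
#' @param x Predictor values (stimulus levels, or `beta_n`).
#' @param y Observed responses.
#' @param variant `"stimulus"` or `"enrs"`.
#' @param n_starts Number of log-spaced starting points (>= 1).
#' @return An object of class `sigmoid_map`: list with `a`, `b`, `variant`,
#'   `r2`, `sse`, `n`, `fitted`, `residuals`, `data`, `convergence`.
#'   Supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @examples
#' x <- c(0, 0.5, 1, 1.5)
#' y <- stimulus_sigmoid(x, a = 3, b = 2)
#' fit <- fit_sigmoid(x, y, "stimulus")
#' glance(fit)
#' @export
fit_sigmoid <- function(x, y, variant = c("stimulus", "enrs"), n_starts = 8) {
  variant <- match.arg(variant)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3)
    abort("need at least 3 distinct predictor values.",
          class = "artstiff_fit_error")
  if (sd(y) == 0)
    abort("constant response: no sigmoid can be identified.",
          class = "artstiff_fit_error")
  closure <- if (variant == "stimulus") c(1, 6) else c(0, 10)
  if (any(y < closure[1] - 1e-8) || any(y > closure[2] + 1e-8))
    warn(sprintf("responses outside the %s codomain closure [%g, %g].",
                 variant, closure[1], closure[2]))
  sse_fun <- function(p) {
    pred <- sigmoid_eval(x, exp(p[1]), exp(p[2]), variant)
    sum((y - pred)^2)
  }
  grid <- expand.grid(la = log(c(0.5, 2, 8, 32)), lb = log(c(0.5, 2)))
  starts <- lapply(seq_len(min(n_starts, nrow(grid))),
                   function(i) as.numeric(grid[i, ]))
  fits <- lapply(starts, function(p0) {
    tryCatch(optim(p0, sse_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits))
    abort("all sigmoid fit starts failed.", class = "artstiff_fit_error")
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  polish <- tryCatch(optim(best$par, sse_fun, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14)),
                     error = function(e) best)
  if (polish$value <= best$value) best <- polish
  a <- exp(best$par[1]); b <- exp(best$par[2])
  fitted <- sigmoid_eval(x, a, b, variant)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(a = a, b = b, variant = variant,
                 r2 = 1 - sse / sst, sse = sse, n = length(x),
                 fitted = fitted, residuals = y - fitted,
                 data = tibble::tibble(x = x, y = y),
                 convergence = best$convergence),
            class = "sigmoid_map")
}

#' @export
print.sigmoid_map <- function(x, ...) {
  cat(sprintf("<sigmoid_map [%s]: a=%.5g, b=%.5g, R^2=%.4f, n=%d>\n",
              x$variant, x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' @export
predict.sigmoid_map <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  sigmoid_eval(x, object$a, object$b, object$variant)
}

#' First-order linear stimulus-response fit
#'
#' Ordinary least-squares line relating a stimulus measure to a response
#' (e.g. stimulus level to mean normalized stiffness), with the coefficient
#' of determination and its two-sided significance probability from the
#' F statistic.
#'
#' @param x Predictor values (>= 2 distinct).
#' @param y Responses, same length.
#' @return An object of class `linear_map`: list with `slope`, `intercept`,
#'   `r2`, `p_value`, `n` and the underlying `lm` fit. Supports [tidy()] and
#'   [glance()].
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2)
    abort("need at least 2 distinct predictor values.",
          class = "artstiff_fit_error")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) == 2 && length(x) > 2) {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared, p_value = unname(p),
                 n = length(x), model = fit),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map: y = %.5g x + %.5g, R^2=%.4f, p=%.3g, n=%d>\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Per-trial summary of normalized stiffness under a protocol
#'
#' Averages `beta_n` over the accepted beats whose reference times fall in
#' each trial's stimulation window, yielding the per-trial table used for
#' stimulus-response fits (mean response per stimulus level).
#'
#' @param series A `stiffness_series` from [normalize_beta()].
#' @param protocol A [stim_protocol()].
#' @return Tibble with `trial`, `level`, `n_beats`, `mean_beta_n`.
#' @export
summarize_trials <- function(series, protocol) {
  purrr::map_dfr(seq_len(nrow(protocol)), function(k) {
    inside <- series$t0 >= protocol$stim_start[k] &
      series$t0 < protocol$stim_end[k]
    tibble::tibble(trial = protocol$trial[k], level = protocol$level[k],
                   n_beats = sum(inside),
                   mean_beta_n = if (any(inside)) mean(series$beta_n[inside])
                                 else NA_real_)
  })
}
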