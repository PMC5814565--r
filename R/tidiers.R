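#' Tidy a fitted sigmoid map
#'
#' @param x A `sigmoid_map` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A tibble with one row per shape parameter.
#' @export
tidy.sigmoid_map <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.sigmoid_map
#' @return `glance()`: a one-row tibble of fit diagnostics.
#' @export
glance.sigmoid_map <- function(x, ...) {
  tibble::tibble(variant = x$variant, r.squared = x$r2, sse = x$sse,
                 nobs = x$n, convergence = x$convergence)
}

#' Tidy a linear stimulus-response fit
#'
#' @param x A `linear_map` from [fit_linear()].
#' @param ... Unused.
#' @return A tibble with intercept and slope rows (estimate, standard error,
#'   t statistic, p value).
#' @export
tidy.linear_map <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.linear_map
#' @return `glance()`: a one-row tibble with R^2, the F-test p value and n.
#' @export
glance.linear_map <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, p.value = x$p_value, nobs = x$n)
}
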