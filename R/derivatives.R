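#' Smoothed-derivative specification
#'
#' Settings for the Savitzky-Golay smoothing differentiator used to obtain
#' the PPG velocity and acceleration. Second derivatives of a measured PPG
#' are noise-dominated without polynomial-window smoothing; 21 ms / order 3
#' is a good default at 1000 Hz for cardiac pulse waveforms.
#'
#' @param window_ms Smoothing window length in milliseconds; converted to an
#'   odd number of samples at the record's sampling rate.
#' @param polyorder Fitting polynomial order; must be below the window length
#'   in samples.
#' @return A list of class `derivative_spec`.
#' @export
derivative_spec <- function(window_ms = 21, polyorder = 3) {
  if (window_ms <= 0 || polyorder < 1)
    abort("`window_ms` must be positive and `polyorder` >= 1.",
          class = "artstiff_parameter_error")
  structure(list(window_ms = window_ms, polyorder = polyorder),
            class = "derivative_spec")
}

#' Smoothed first and second derivatives of a sampled signal
#'
#' Applies Savitzky-Golay differentiation filters to obtain the first and
#' second time-derivatives. The operator is linear (additivity holds) and
#' returns derivatives in signal units per second and per second squared.
#'
#' @param x Signal samples (typically PPG).
#' @param fs Sampling rate, Hz.
#' @param spec A [derivative_spec()].
#' @return A list with numeric vectors `d1` and `d2`, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' d <- compute_derivatives(sin(2 * pi * t), fs = 1000)
#' @export
compute_derivatives <- function(x, fs, spec = derivative_spec()) {
  n_win <- round(spec$window_ms / 1000 * fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  n_win <- max(n_win, spec$polyorder + 2 + (spec$polyorder %% 2 == 1))
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win >= length(x))
    abort("smoothing window is longer than the signal.",
          class = "artstiff_parameter_error")
  list(
    d1 = signal::sgolayfilt(x, p = spec$polyorder, n = n_win, m = 1, ts = 1 / fs),
    d2 = signal::sgolayfilt(x, p = spec$polyorder, n = n_win, m = 2, ts = 1 / fs)
  )
}
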