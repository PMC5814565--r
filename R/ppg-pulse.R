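#' Pulse shape parameters for the synthetic PPG generator
#'
#' The synthetic photoplethysmogram pulse is a sum of two circular
#' (von Mises-shaped) lobes over the cardiac cycle: a systolic lobe and a
#' smaller, wider dicrotic lobe. Because each lobe is a smooth periodic
#' function of cycle phase, consecutive pulses of equal period are continuous
#' in value and in all derivatives at beat junctions, and the first and
#' second time-derivatives are available in closed form.
#'
#' Widths are expressed as an approximate standard deviation in fractions of
#' the cycle; internally the lobe concentration is `1 / (2 * pi * width)^2`.
#'
#' @param systolic_frac Cycle fraction at which the systolic lobe peaks.
#' @param systolic_width Width of the systolic lobe (cycle fraction, > 0).
#' @param dicrotic_frac Cycle fraction of the dicrotic lobe peak.
#' @param dicrotic_width Width of the dicrotic lobe (cycle fraction, > 0).
#' @param dicrotic_amp Dicrotic lobe amplitude relative to the systolic lobe.
#' @return A list of class `ppg_pulse_shape`.
#' @export
ppg_pulse_shape <- function(systolic_frac = 0.32, systolic_width = 0.037,
                            dicrotic_frac = 0.62, dicrotic_width = 0.05,
                            dicrotic_amp = 0.45) {
  if (systolic_width <= 0 || dicrotic_width <= 0)
    abort("pulse lobe widths must be strictly positive.",
          class = "artstiff_parameter_error")
  if (dicrotic_amp < 0)
    abort("`dicrotic_amp` must be non-negative.", class = "artstiff_parameter_error")
  structure(list(
    systolic_frac = systolic_frac,
    systolic_kappa = 1 / (2 * pi * systolic_width)^2,
    dicrotic_frac = dicrotic_frac,
    dicrotic_kappa = 1 / (2 * pi * dicrotic_width)^2,
    dicrotic_amp = dicrotic_amp
  ), class = "ppg_pulse_shape")
}

# raw (unnormalized) pulse and its phase-domain derivative machinery
pulse_raw <- function(theta, shape, deriv = 0) {
  lobe <- function(a, kappa, centre) {
    d <- theta - centre
    e <- a * exp(kappa * (cos(d) - 1))
    switch(as.character(deriv),
           "0" = e,
           "1" = e * (-kappa * sin(d)),
           "2" = e * ((kappa * sin(d))^2 - kappa * cos(d)))
  }
  lobe(1, shape$systolic_kappa, 2 * pi * shape$systolic_frac) +
    lobe(shape$dicrotic_amp, shape$dicrotic_kappa, 2 * pi * shape$dicrotic_frac)
}

# min and max of the raw pulse over one cycle, to high precision
pulse_range <- function(shape) {
  grid <- seq(0, 2 * pi, length.out = 721)
  v <- pulse_raw(grid, shape)
  refine <- function(i, maximum) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    optimize(function(th) pulse_raw(th, shape), c(lo, hi),
             maximum = maximum, tol = 1e-12)
  }
  mx <- refine(which.max(v), TRUE)
  mn <- refine(which.min(v), FALSE)
  c(min = mn$objective, max = mx$objective)
}

#' Evaluate one synthetic PPG pulse
#'
#' Evaluates the two-lobe pulse model (or its first or second
#' time-derivative, in closed form) at times `t` seconds after the beat
#' reference time. The pulse is normalized so that its minimum over the cycle
#' is 0 and its peak value is `amplitude`.
#'
#' @param t Times in seconds relative to beat onset (the R-wave); values are
#'   interpreted modulo `period`, so the waveform is periodic.
#' @param period Cardiac period in seconds; must lie in `(0.2, 3)`.
#' @param amplitude Peak pulse amplitude (PPG arbitrary units).
#' @param shape A [ppg_pulse_shape()].
#' @param deriv 0 for the pulse, 1 or 2 for its time-derivatives
#'   (units/s, units/s^2).
#' @return Numeric vector of pulse (or derivative) values.
#' @examples
#' t <- seq(0, 0.8, by = 0.001)
#' p <- ppg_pulse(t, period = 0.8)
#' max(p)
#' @export
ppg_pulse <- function(t, period, amplitude = 1, shape = ppg_pulse_shape(),
                      deriv = 0) {
  if (!is.numeric(period) || period <= 0.2 || period > 3)
    abort("`period` must be a physiologic cardiac period in (0.2, 3] s.",
          class = "artstiff_parameter_error")
  if (!deriv %in% 0:2)
    abort("`deriv` must be 0, 1 or 2.", class = "artstiff_parameter_error")
  rng <- pulse_range(shape)
  scale <- amplitude / (rng["max"] - rng["min"])
  theta <- 2 * pi * t / period
  w <- 2 * pi / period
  v <- pulse_raw(theta, shape, deriv = deriv) * w^deriv * scale
  if (deriv == 0) v <- v - rng["min"] * scale
  unname(v)
}
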