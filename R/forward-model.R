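#' Viscoelastic parameters of the log-linearized arterial model
#'
#' The model relates blood pressure to the PPG waveform (taken as
#' proportional to arterial-diameter strain) as
#' \deqn{P_b(t) = \mu \ddot P_l(t) + \eta \dot P_l(t) +
#'       \exp\{\beta P_l(t) + P_{b\beta_0} + P_{b\beta nl}\},}
#' where \eqn{\mu} is the arterial-wall inertia, \eqn{\eta} the viscosity and
#' \eqn{\beta} the stiffness index; \eqn{P_{b\beta_0}} is the standard
#' (log-)blood-pressure offset and \eqn{P_{b\beta nl}} a venous pressure
#' component, carried here as a constant exponent offset so that its
#' within-beat difference vanishes and the stiffness index is exactly
#' identifiable.
#'
#' `beta_A` is the linearized stiffness of the first estimation step,
#' \eqn{\beta_A = C_1 \exp\{P_{b\beta_0} + P_{b\beta nl}(0)\}} with
#' \eqn{C_1 = \beta} for a constant venous term; it is derived, not free, and
#' is computed by [beta_A_true()].
#'
#' @param mu Inertia, mmHg s^2 per PPG unit (>= 0).
#' @param eta Viscosity, mmHg s per PPG unit (>= 0).
#' @param beta Stiffness index, per PPG unit (> 0 for physiologic simulation).
#' @param p_b0 Standard-pressure exponent offset (dimensionless;
#'   `exp(p_b0 + p_bnl_const)` is the zero-strain elastic pressure in mmHg).
#' @param p_bnl_const Constant venous exponent offset (dimensionless).
#' @return A list of class `viscoelastic_params`.
#' @examples
#' viscoelastic_params()
#' @export
viscoelastic_params <- function(mu = 0.05, eta = 0.8, beta = 1.5,
                                p_b0 = log(60), p_bnl_const = 0) {
  if (mu < 0 || eta < 0)
    abort("`mu` and `eta` must be non-negative.", class = "artstiff_parameter_error")
  if (beta <= 0)
    abort("`beta` must be strictly positive.", class = "artstiff_parameter_error")
  if (!is.finite(exp(p_b0 + p_bnl_const)) || exp(p_b0 + p_bnl_const) <= 0)
    abort("exp(p_b0 + p_bnl_const) must be a positive finite pressure.",
          class = "artstiff_parameter_error")
  structure(list(mu = mu, eta = eta, beta = beta,
                 p_b0 = p_b0, p_bnl_const = p_bnl_const),
            class = "viscoelastic_params")
}

#' @rdname viscoelastic_params
#' @param params A `viscoelastic_params` object.
#' @export
beta_A_true <- function(params) {
  params$beta * exp(params$p_b0 + params$p_bnl_const)
}

#' @export
print.viscoelastic_params <- function(x, ...) {
  cat(sprintf(
    "<viscoelastic_params: mu=%.4g mmHg s^2/u, eta=%.4g mmHg s/u, beta=%.4g /u, exp offset=%.4g (%.4g mmHg)>\n",
    x$mu, x$eta, x$beta, x$p_b0 + x$p_bnl_const, exp(x$p_b0 + x$p_bnl_const)))
  invisible(x)
}

#' Forward viscoelastic model: blood pressure from PPG
#'
#' Evaluates the log-linearized viscoelastic model elementwise:
#' `bp = mu * d2 + eta * d1 + exp(beta * ppg + p_b0 + p_bnl_const)`.
#'
#' @param ppg PPG samples (arbitrary units).
#' @param d1,d2 First and second time-derivatives of the PPG
#'   (units/s, units/s^2), same length as `ppg`.
#' @param params A [viscoelastic_params()] object.
#' @param exp_cap Cap on the exponent; exceeding it raises a simulation error
#'   rather than silently overflowing.
#' @return Blood-pressure samples in mmHg.
#' @examples
#' p <- viscoelastic_params(mu = 0, eta = 0, beta = 1, p_b0 = log(80))
#' forward_bp(0.1, 0, 0, p)  # 80 * exp(0.1)
#' @export
forward_bp <- function(ppg, d1, d2, params, exp_cap = 50) {
  if (length(d1) != length(ppg) || length(d2) != length(ppg))
    abort("`ppg`, `d1` and `d2` must have equal length.",
          class = "artstiff_parameter_error")
  expo <- params$beta * ppg + params$p_b0 + params$p_bnl_const
  if (any(expo > exp_cap))
    abort(sprintf("elastic exponent exceeds cap %g; unphysiologic parameters.", exp_cap),
          class = "artstiff_simulation_error")
  params$mu * d2 + params$eta * d1 + exp(expo)
}

#' Stiffness as a sigmoid function of stimulus level
#'
#' Couples the arterial stiffness index to the electrocutaneous stimulus
#' level `S` through the bounded stimulus-response sigmoid
#' `target = 10 / (1 + exp(a * S^-b)) + 1`, with the `S = 0` value defined by
#' its limit, 1. The returned stiffness is `beta_rest * target`, so the
#' resting stiffness is recovered exactly at zero stimulation and stiffness
#' saturates at `6 * beta_rest` for very strong stimuli.
#'
#' @param S Stimulus level(s), as multiples of the standard current
#'   amplitude (>= 0).
#' @param a,b Sigmoid shape parameters (> 0).
#' @param beta_rest Resting stiffness index (> 0), per PPG unit.
#' @return Stiffness index values, per PPG unit.
#' @examples
#' stiffness_from_stimulus(c(0, 0.5, 1, 1.5), a = 3, b = 1, beta_rest = 1.5)
#' @export
stiffness_from_stimulus <- function(S, a = 3, b = 1, beta_rest = 1.5) {
  if (a <= 0 || b <= 0 || beta_rest <= 0)
    abort("`a`, `b` and `beta_rest` must be strictly positive.",
          class = "artstiff_parameter_error")
  if (any(S < 0))
    abort("stimulus levels must be non-negative.", class = "artstiff_parameter_error")
  beta_rest * stimulus_sigmoid(S, a, b)
}
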