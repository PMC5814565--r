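#' Synthesize a waveform record with known ground truth
#'
#' Generates a synchronized ECG / blood-pressure / PPG record from the
#' forward viscoelastic model under a stimulation protocol, together with a
#' per-beat ground-truth ledger. The ECG is a triangular QRS template train
#' marking each beat onset; the PPG is a train of smooth two-lobe pulses; the
#' blood pressure is the forward model evaluated with the analytic PPG
#' derivatives (so the simulator truth is exact) plus i.i.d. Gaussian
#' measurement noise. Within each trial the stiffness index follows the
#' stimulus level through the bounded sigmoid of
#' [stiffness_from_stimulus()].
#'
#' @param protocol A [stim_protocol()]; sets the stimulus level of each beat.
#' @param fs Sampling rate in Hz (>= 250).
#' @param heart_rate Heart rate in beats per minute (constant).
#' @param params Resting-state [viscoelastic_params()]; `params$beta` is the
#'   resting stiffness scaled by the stimulus coupling.
#' @param coupling Named list or vector with sigmoid shape `a` and `b` (> 0)
#'   coupling stimulus level to stiffness.
#' @param beta_schedule Optional explicit per-beat stiffness values
#'   overriding the coupling; must have one value per full beat.
#' @param sigma_bp Standard deviation of additive Gaussian blood-pressure
#'   noise, mmHg.
#' @param ppg_amplitude Resting PPG pulse amplitude, arbitrary units.
#' @param ppg_attenuation Fractional PPG amplitude reduction per unit
#'   stimulus level (vasoconstriction decreases pulse amplitude); 0 disables.
#' @param shape A [ppg_pulse_shape()].
#' @param duration Record duration in seconds; defaults to the protocol
#'   duration.
#' @param seed Integer seed; the same seed reproduces the record exactly.
#' @param keep_derivatives If `TRUE`, the analytic PPG derivatives are kept
#'   in the record as columns `d1_true`, `d2_true`.
#' @return A list of class `synth_record` with elements `record`
#'   (a [waveform_record()]), `truth` (tibble: `beat`, `t0`, `t0_sample`,
#'   `S`, `mu`, `eta`, `beta`, `beta_A`, `amplitude`), `protocol`, `params`.
#' @examples
#' synth <- synthesize_record(stim_protocol(levels = c(0, 1.5)), fs = 250,
#'                            sigma_bp = 0, seed = 1)
#' nrow(synth$truth)
#' @export
synthesize_record <- function(protocol = stim_protocol(), fs = 1000,
                              heart_rate = 70,
                              params = viscoelastic_params(),
                              coupling = list(a = 3, b = 1),
                              beta_schedule = NULL,
                              sigma_bp = 0.5,
                              ppg_amplitude = 0.5, ppg_attenuation = 0,
                              shape = ppg_pulse_shape(),
                              duration = NULL, seed = NULL,
                              keep_derivatives = FALSE) {
  if (fs < 250)
    abort("`fs` must be at least 250 Hz.", class = "artstiff_simulation_error")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  duration <- duration %||% protocol_duration(protocol)
  period <- 60 / heart_rate
  n <- round(duration * fs)
  time <- (seq_len(n) - 1) / fs

  # full beats fit entirely inside the record; a trailing partial beat may
  # remain and reuses the last full beat's parameters
  n_full <- floor(duration / period + 1e-9)
  if (n_full < 1)
    abort("record too short for a single beat.", class = "artstiff_simulation_error")
  t0 <- (seq_len(n_full) - 1) * period
  S <- stimulus_level_at(protocol, t0)
  if (is.null(beta_schedule)) {
    beta_k <- stiffness_from_stimulus(S, a = coupling[["a"]], b = coupling[["b"]],
                                      beta_rest = params$beta)
  } else {
    if (length(beta_schedule) != n_full)
      abort(sprintf("`beta_schedule` has %d values but the record holds %d full beats.",
                    length(beta_schedule), n_full),
            class = "artstiff_simulation_error")
    beta_k <- beta_schedule
  }
  amp_k <- ppg_amplitude * (1 - ppg_attenuation * S)
  if (any(amp_k <= 0))
    abort("PPG attenuation drives the pulse amplitude to zero or below.",
          class = "artstiff_simulation_error")

  ib <- pmin(floor(time / period + 1e-12), n_full - 1) + 1  # beat of each sample
  t_rel <- time - (ib - 1) * period
  unit0 <- ppg_pulse(t_rel, period, 1, shape, deriv = 0)
  unit1 <- ppg_pulse(t_rel, period, 1, shape, deriv = 1)
  unit2 <- ppg_pulse(t_rel, period, 1, shape, deriv = 2)
  ppg <- amp_k[ib] * unit0
  d1 <- amp_k[ib] * unit1
  d2 <- amp_k[ib] * unit2

  expo <- beta_k[ib] * ppg + params$p_b0 + params$p_bnl_const
  if (any(expo > 50))
    abort("elastic exponent exceeds 50; unphysiologic simulation parameters.",
          class = "artstiff_simulation_error")
  bp <- params$mu * d2 + params$eta * d1 + exp(expo)
  if (sigma_bp > 0) bp <- bp + rnorm(n, sd = sigma_bp)

  # triangular QRS template (20 ms wide, unit height) at each beat onset
  ecg <- numeric(n)
  half <- max(1L, round(0.010 * fs))
  t0_sample <- round(t0 * fs) + 1L
  for (k in seq_len(n_full)) {
    idx <- (t0_sample[k] - half):(t0_sample[k] + half)
    ok <- idx >= 1 & idx <= n
    ecg[idx[ok]] <- pmax(ecg[idx[ok]], 1 - abs(idx[ok] - t0_sample[k]) / half)
  }

  rec_extra <- if (keep_derivatives) list(d1_true = d1, d2_true = d2) else list()
  record <- rlang::exec(waveform_record,
                        ecg = ecg, bp = bp, ppg = ppg, fs = fs, time = time,
                        meta = list(source = "synthetic", heart_rate = heart_rate,
                                    sigma_bp = sigma_bp, seed = seed),
                        !!!rec_extra)
  truth <- tibble::tibble(
    beat = seq_len(n_full),
    t0 = t0,
    t0_sample = t0_sample,
    S = S,
    mu = params$mu,
    eta = params$eta,
    beta = beta_k,
    beta_A = beta_k * exp(params$p_b0 + params$p_bnl_const),
    amplitude = amp_k
  )
  structure(list(record = record, truth = truth, protocol = protocol,
                 params = params),
            class = "synth_record")
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("<synth_record: %d beats, %.4g s at %g Hz, sigma_bp=%g mmHg>\n",
              nrow(x$truth), record_duration(x$record),
              record_fs(x$record), record_meta(x$record)$sigma_bp))
  invisible(x)
}
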