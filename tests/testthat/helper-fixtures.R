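# Shared fixtures and independent oracles, built in code at test time.

# Independent transcription of the forward model, kept deliberately separate
# from forward_bp(): elementwise evaluation with scalar arithmetic in a loop.
oracle_forward_bp <- function(ppg, d1, d2, mu, eta, beta, c0) {
  out <- numeric(length(ppg))
  for (i in seq_along(ppg))
    out[i] <- mu * d2[i] + eta * d1[i] + exp(beta * ppg[i] + c0)
  out
}

# One beat sampled from the full nonlinear model with analytic derivatives.
make_model_beat <- function(params = viscoelastic_params(), fs = 1000,
                            period = 60 / 70, amplitude = 0.5,
                            sigma_bp = 0, shape = ppg_pulse_shape()) {
  t <- seq(0, period - 1 / fs, by = 1 / fs)
  ppg <- ppg_pulse(t, period, amplitude, shape)
  d1 <- ppg_pulse(t, period, amplitude, shape, deriv = 1)
  d2 <- ppg_pulse(t, period, amplitude, shape, deriv = 2)
  bp <- forward_bp(ppg, d1, d2, params)
  if (sigma_bp > 0) bp <- bp + rnorm(length(bp), sd = sigma_bp)
  list(bp = bp, ppg = ppg, d1 = d1, d2 = d2, t = t, params = params)
}

# One beat sampled exactly from the differenced linear (step-1) model.
make_linear_beat <- function(mu = 0.05, eta = 0.8, beta_A = 60, fs = 1000,
                             period = 60 / 70, amplitude = 0.5,
                             bp0 = 80) {
  b <- make_model_beat(fs = fs, period = period, amplitude = amplitude)
  bp <- bp0 + mu * (b$d2 - b$d2[1]) + eta * (b$d1 - b$d1[1]) +
    beta_A * (b$ppg - b$ppg[1])
  list(bp = bp, ppg = b$ppg, d1 = b$d1, d2 = b$d2,
       mu = mu, eta = eta, beta_A = beta_A)
}

# Join per-beat estimates with the simulator's ground-truth ledger.
join_truth <- function(estimates, truth) {
  dplyr::inner_join(tibble::as_tibble(estimates),
                    dplyr::select(truth, t0_sample, true_mu = mu,
                                  true_eta = eta, true_beta = beta,
                                  true_beta_A = beta_A, S),
                    by = "t0_sample")
}

# Small waveform CSV written to a temp file.
write_record_fixture <- function(n = 1000, fs = 1000, path = tempfile(fileext = ".csv")) {
  t <- (seq_len(n) - 1) / fs
  df <- data.frame(time = t, ecg = sin(2 * pi * t), bp = 80 + 10 * cos(2 * pi * t),
                   ppg = 0.5 + 0.4 * sin(2 * pi * t))
  readr::write_csv(df, path, progress = FALSE)
  path
}
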