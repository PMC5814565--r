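#' Electrocutaneous stimulation protocol
#'
#' Builds the trial schedule of a stimulation experiment block. Each trial is
#' rest, then continuous stimulation at a given level, then a pain-evaluation
#' pause. The default is the seven-trial block used throughout the package:
#' 20 s rest + 24 s stimulation + 20 s evaluation per trial (64 s, 448 s per
#' block) with stimulus levels 1.5, 1.0, 0.5, 0, 0.5, 1.0, 1.5 times the
#' standard current amplitude, strongest first.
#'
#' @param levels Stimulus levels, one per trial (multiples of the standard
#'   amplitude, >= 0).
#' @param rest_s,stim_s,eval_s Durations of the rest, stimulation and
#'   evaluation phases in seconds (recycled across trials).
#' @return A tibble of class `stim_protocol` with columns `trial`, `level`,
#'   `trial_start`, `stim_start`, `stim_end`, `trial_end` (seconds).
#' @examples
#' stim_protocol()
#' protocol_duration(stim_protocol())  # 448
#' @export
stim_protocol <- function(levels = c(1.5, 1.0, 0.5, 0, 0.5, 1.0, 1.5),
                          rest_s = 20, stim_s = 24, eval_s = 20) {
  if (any(levels < 0))
    abort("stimulus levels must be non-negative.", class = "artstiff_parameter_error")
  n <- length(levels)
  rest_s <- rep_len(rest_s, n); stim_s <- rep_len(stim_s, n)
  eval_s <- rep_len(eval_s, n)
  if (any(c(rest_s, stim_s, eval_s) < 0))
    abort("phase durations must be non-negative.", class = "artstiff_parameter_error")
  dur <- rest_s + stim_s + eval_s
  trial_start <- cumsum(c(0, head(dur, -1)))
  x <- tibble::tibble(
    trial = seq_len(n),
    level = levels,
    trial_start = trial_start,
    stim_start = trial_start + rest_s,
    stim_end = trial_start + rest_s + stim_s,
    trial_end = trial_start + dur
  )
  class(x) <- c("stim_protocol", class(x))
  x
}

#' @rdname stim_protocol
#' @param protocol A `stim_protocol`.
#' @export
protocol_duration <- function(protocol) max(protocol$trial_end)

#' Stimulus level at given times
#'
#' @param protocol A [stim_protocol()].
#' @param t Times in seconds from block start.
#' @return The stimulus level active at each time (0 outside stimulation
#'   windows); windows are half-open `[stim_start, stim_end)`.
#' @export
stimulus_level_at <- function(protocol, t) {
  out <- numeric(length(t))
  for (k in seq_len(nrow(protocol))) {
    inside <- t >= protocol$stim_start[k] & t < protocol$stim_end[k]
    out[inside] <- protocol$level[k]
  }
  out
}

#' Baseline (no-stimulation) window of a protocol
#'
#' Returns the stimulation window of the first zero-level trial, the natural
#' baseline for normalizing the stiffness index, as a
#' `c(start = , end = )` pair in seconds.
#'
#' @param protocol A [stim_protocol()].
#' @return Named numeric vector `start`, `end` (seconds).
#' @export
protocol_baseline_window <- function(protocol) {
  zero <- which(protocol$level == 0)
  if (!length(zero))
    abort("protocol has no zero-level trial to use as baseline.",
          class = "artstiff_parameter_error")
  k <- zero[1]
  c(start = protocol$stim_start[k], end = protocol$stim_end[k])
}
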