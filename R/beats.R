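#' Detect ECG R-peaks
#'
#' A Pan-Tompkins-style detector: band-pass filter (5-25 Hz), squared
#' derivative, 150 ms moving-window energy integration, adaptive thresholding
#' with a 250 ms refractory period, and final refinement of each fiducial
#' point to the local ECG maximum. Deterministic for a fixed input, and
#' invariant to adding a constant offset to the ECG.
#'
#' @param ecg ECG samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum separation between detected peaks, seconds.
#' @param band Pass band of the pre-filter, Hz (length 2).
#' @param min_rr,max_rr Physiologic bounds on the R-R interval, seconds.
#'   Intervals outside the bounds are flagged in the `rr_ok` attribute of the
#'   result, not dropped.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based), with attribute `rr_ok` flagging inter-peak intervals within
#'   the physiologic bounds.
#' @examples
#' ecg <- rep(0, 5000); ecg[c(1000, 2000, 3000, 4000)] <- 1
#' detect_r_peaks(ecg, fs = 1000)
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25, band = c(5, 25),
                           min_rr = 0.3, max_rr = 2.0) {
  n <- length(ecg)
  if (n < 2 * fs)
    abort("ECG must be at least 2 s long.", class = "artstiff_segmentation_error")
  if (!all(is.finite(ecg)))
    abort("ECG contains non-finite samples.", class = "artstiff_data_error")
  centred <- ecg - median(ecg)
  if (max(abs(centred)) == 0)
    abort("no R-peaks found: flat ECG.", class = "artstiff_segmentation_error")
  bf <- signal::butter(2, pmin(band / (fs / 2), 0.99), type = "pass")
  f <- signal::filtfilt(bf, centred)
  energy <- (c(0, diff(f)) * fs)^2
  w <- max(3L, round(0.15 * fs))
  env <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  env[!is.finite(env)] <- 0

  # local maxima of the energy envelope above an adaptive threshold
  thr <- 0.25 * as.numeric(quantile(env, 0.999))
  if (thr <= 0)
    abort("no R-peaks found: no ECG energy above threshold.",
          class = "artstiff_segmentation_error")
  is_max <- env >= thr &
    env >= c(-Inf, env[-n]) & env > c(env[-1], -Inf)
  cand <- which(is_max)
  if (!length(cand))
    abort("no R-peaks found.", class = "artstiff_segmentation_error")

  # greedy refractory pruning, keeping the taller of clashing candidates
  ord <- cand[order(env[cand], decreasing = TRUE)]
  refr <- round(refractory_s * fs)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= refr))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)

  # refine to the raw ECG maximum near each envelope peak
  half <- round(0.10 * fs)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(centred[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; enforce refractory once more
  if (length(peaks) > 1) {
    ok <- c(TRUE, diff(peaks) >= refr)
    peaks <- peaks[ok]
  }
  if (!length(peaks))
    abort("no R-peaks found.", class = "artstiff_segmentation_error")
  rr <- diff(peaks) / fs
  attr(peaks, "rr_ok") <- rr >= min_rr & rr <= max_rr
  peaks
}

#' Segment a record into cardiac cycles
#'
#' Partitions the record into one window per R-R interval. Each beat window is
#' the half-open sample span `[start_sample, end_sample)` from one R-peak to
#' the next, with the leading R-peak as the within-beat reference time t0 and
#' the arithmetic mean of blood pressure over the window as `mean_bp`. The
#' partial cycles before the first and after the last detected R-peak are
#' discarded.
#'
#' @param record A [waveform_record()].
#' @param r_peaks Optional R-peak sample indices; detected with
#'   [detect_r_peaks()] when omitted.
#' @return A tibble with one row per beat: `beat`, `start_sample`,
#'   `end_sample` (half-open), `t0_sample`, `t0` (seconds), `rr` (seconds)
#'   and `mean_bp` (mmHg).
#' @export
segment_beats <- function(record, r_peaks = NULL) {
  fs <- record_fs(record)
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(record$ecg, fs)
  if (length(r_peaks) < 2)
    abort("need at least 2 R-peaks to segment beats.",
          class = "artstiff_segmentation_error")
  r_peaks <- sort(as.integer(r_peaks))
  start <- r_peaks[-length(r_peaks)]
  end <- r_peaks[-1]
  tibble::tibble(
    beat = seq_along(start),
    start_sample = start,
    end_sample = end,
    t0_sample = start,
    t0 = record$time[start],
    rr = (end - start) / fs,
    mean_bp = vapply(seq_along(start),
                     function(k) mean(record$bp[start[k]:(end[k] - 1L)]),
                     numeric(1))
  )
}
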