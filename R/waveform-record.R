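#' Construct a synchronized waveform record
#'
#' A waveform record holds simultaneously sampled ECG, continuous blood
#' pressure (mmHg) and photoplethysmogram (PPG, arbitrary units) channels on a
#' uniform time grid. It is a tibble with columns `time`, `ecg`, `bp`, `ppg`
#' (plus any extra columns, e.g. ground-truth PPG derivatives from the
#' simulator) and carries the sampling rate and free-form provenance metadata
#' as attributes.
#'
#' @param time Sample times in seconds, uniformly spaced. If `NULL`, generated
#'   as `(seq_along(bp) - 1) / fs`.
#' @param ecg ECG channel, arbitrary units.
#' @param bp Continuous blood pressure, mmHg.
#' @param ppg Photoplethysmogram, arbitrary units.
#' @param fs Sampling rate in Hz.
#' @param meta Named list of provenance metadata (subject id, protocol label, ...).
#' @param ... Additional equal-length columns to carry along.
#'
#' @return A `waveform_record` tibble.
#' @examples
#' rec <- waveform_record(ecg = rnorm(100), bp = rep(80, 100),
#'                        ppg = rep(0.5, 100), fs = 100)
#' record_fs(rec)
#' @export
waveform_record <- function(ecg, bp, ppg, fs, time = NULL, meta = list(), ...) {
  if (is.null(time)) time <- (seq_along(bp) - 1) / fs
  x <- tibble::tibble(time = time, ecg = ecg, bp = bp, ppg = ppg, ...)
  attr(x, "fs") <- fs
  attr(x, "meta") <- meta
  class(x) <- c("waveform_record", class(x))
  validate_waveform_record(x)
}

#' Validate a waveform record
#'
#' Checks the record invariants: equal channel lengths of at least 2, a
#' strictly increasing time grid with spacing `1/fs` within tolerance, and
#' finite blood-pressure and PPG values.
#'
#' @param x A `waveform_record`.
#' @param tol Relative tolerance on the sample spacing.
#' @return `x`, invisibly validated (returned unchanged).
#' @export
validate_waveform_record <- function(x, tol = 1e-6) {
  fs <- attr(x, "fs")
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort("`fs` must be a single positive number.", class = "artstiff_format_error")
  for (ch in c("time", "ecg", "bp", "ppg"))
    if (!ch %in% names(x))
      abort(paste0("record is missing channel `", ch, "`."),
            class = "artstiff_format_error")
  if (nrow(x) < 2)
    abort("record must contain at least 2 samples.", class = "artstiff_format_error")
  dt <- diff(x$time)
  if (any(!is.finite(x$time)) || any(dt <= 0))
    abort("`time` must be finite and strictly increasing.",
          class = "artstiff_format_error")
  if (any(abs(dt - 1 / fs) > tol / fs))
    abort("`time` is not uniformly sampled at `fs` within tolerance.",
          class = "artstiff_format_error")
  if (any(!is.finite(x$bp)))
    abort("`bp` contains non-finite values.", class = "artstiff_data_error")
  if (any(!is.finite(x$ppg)))
    abort("`ppg` contains non-finite values.", class = "artstiff_data_error")
  x
}

#' Sampling rate and metadata accessors
#'
#' @param x A `waveform_record`.
#' @return `record_fs()` the sampling rate in Hz; `record_meta()` the metadata
#'   list; `record_duration()` the record duration in seconds.
#' @export
record_fs <- function(x) attr(x, "fs")

#' @rdname record_fs
#' @export
record_meta <- function(x) attr(x, "meta") %||% list()

#' @rdname record_fs
#' @export
record_duration <- function(x) nrow(x) / record_fs(x)

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record: %d samples, %.6g Hz, %.4g s>\n",
              nrow(x), record_fs(x), record_duration(x)))
  NextMethod()
}

# interpolate short NaN gaps in a channel; error on long runs
fill_short_gaps <- function(v, channel, fs, gap_limit_ms = 20) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  r <- rle(bad)
  max_run <- max(r$lengths[r$values])
  limit <- max(1L, floor(gap_limit_ms / 1000 * fs))
  if (max_run > limit)
    abort(sprintf("channel `%s` has a %d-sample non-finite gap (limit %d samples).",
                  channel, max_run, limit),
          class = "artstiff_data_error")
  if (bad[1] || bad[length(v)])
    abort(sprintf("channel `%s` starts or ends with non-finite samples.", channel),
          class = "artstiff_data_error")
  warn(sprintf("channel `%s`: linearly interpolated %d non-finite sample(s) (gaps <= %g ms).",
               channel, sum(bad), gap_limit_ms))
  zoo::na.approx(ifelse(is.finite(v), v, NA_real_), na.rm = FALSE)
}

#' Read a waveform record from a delimited text file
#'
#' The primary on-disk format is a single CSV (or TSV) with a header naming a
#' time column and the three channels. A configuration list can remap channel
#' names, declare the sampling rate, and set the non-finite gap limit. Short
#' runs of NA/NaN (at most `gap_limit_ms`) are linearly interpolated with a
#' warning; longer runs are a data error.
#'
#' @param path Path to a delimited text file with a header.
#' @param config Optional list with elements `channels` (named list mapping
#'   `time`/`ecg`/`bp`/`ppg` to column names in the file), `fs` (expected
#'   sampling rate, checked against the time column), `units` (named list,
#'   attached to metadata), and `gap_limit_ms`.
#' @param gap_limit_ms Maximum non-finite gap, in milliseconds, that is
#'   repaired by linear interpolation; overridden by `config$gap_limit_ms`.
#' @return A validated [waveform_record()].
#' @export
read_waveform_csv <- function(path, config = NULL, gap_limit_ms = 20) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "artstiff_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map <- config$channels %||% list()
  cols <- vapply(c("time", "ecg", "bp", "ppg"),
                 function(ch) map[[ch]] %||% ch, character(1))
  missing <- cols[!cols %in% names(df)]
  if (length(missing))
    abort(paste0("file is missing channel column(s): ",
                 paste(missing, collapse = ", ")),
          class = "artstiff_format_error")
  time <- df[[cols[["time"]]]]
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    abort("time column must be finite and strictly increasing.",
          class = "artstiff_format_error")
  fs <- config$fs %||% (1 / median(diff(time)))
  gap_limit_ms <- config$gap_limit_ms %||% gap_limit_ms
  chans <- lapply(setNames(cols[c("ecg", "bp", "ppg")], c("ecg", "bp", "ppg")),
                  function(cl) fill_short_gaps(df[[cl]], cl, fs, gap_limit_ms))
  meta <- list(source = path)
  if (!is.null(config$units)) meta$units <- config$units
  waveform_record(ecg = chans$ecg, bp = chans$bp, ppg = chans$ppg,
                  fs = fs, time = time, meta = meta)
}

#' Write a waveform record to CSV
#'
#' Writes the `time`, `ecg`, `bp` and `ppg` columns with full double
#' precision, so that `read_waveform_csv()` round-trips the record.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(record),
                                 dplyr::all_of(c("time", "ecg", "bp", "ppg"))),
                   path, progress = FALSE)
  invisible(path)
}
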