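#' Write and read per-beat estimate tables
#'
#' `write_beat_estimates()` writes one row per beat (beat index, reference
#' time t0, window span, mean blood pressure, the estimated parameters, the
#' reconstruction R^2, the acceptance flag and any per-beat note) as CSV with
#' full double precision, so the table round-trips losslessly well beyond 12
#' significant digits. `read_beat_estimates()` reads such a table back as a
#' `beat_estimates` tibble.
#'
#' @param estimates A non-empty `beat_estimates` tibble from
#'   [estimate_record()].
#' @param path Output (input) CSV path.
#' @return `write_beat_estimates()` returns `path` invisibly;
#'   `read_beat_estimates()` returns the tibble.
#' @export
write_beat_estimates <- function(estimates, path) {
  if (is.null(estimates) || nrow(estimates) == 0)
    abort("`estimates` must contain at least one beat.",
          class = "artstiff_io_error")
  ok <- tryCatch({
    readr::write_csv(tibble::as_tibble(estimates), path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort(paste0("cannot write beat estimates: ", conditionMessage(ok)),
          class = "artstiff_io_error")
  invisible(path)
}

#' @rdname write_beat_estimates
#' @export
read_beat_estimates <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "artstiff_io_error")
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("beat_estimates", class(out))
  out
}
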