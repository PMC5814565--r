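#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one list, filling in
#' the documented defaults. A configuration can equally be read from a YAML
#' or JSON file with [read_pipeline_config()]; values given there override
#' the defaults.
#'
#' @param input Path to a waveform CSV, or `NULL` to synthesize a record
#'   (see `synth`).
#' @param out_dir Output directory for `beats.csv`, `series.csv`,
#'   `trials.csv`, `maps.json` and `run_log.txt`.
#' @param channels Optional named list remapping `time`/`ecg`/`bp`/`ppg` to
#'   file column names.
#' @param fs Expected sampling rate in Hz (checked/attached when reading).
#' @param baseline `c(start, end)` seconds of the no-stimulation window used
#'   to normalize beta; defaults to the protocol's zero-level stimulation
#'   window.
#' @param protocol Optional list of [stim_protocol()] arguments (`levels`,
#'   `rest_s`, `stim_s`, `eval_s`); defaults to the standard 7-trial block
#'   when a record is synthesized.
#' @param synth Optional list of [synthesize_record()] arguments used when
#'   `input` is `NULL`.
#' @param r2_gate Acceptance threshold on the reconstruction R^2.
#' @param min_mask_samples Minimum step-2 mask size.
#' @param window_ms,polyorder Savitzky-Golay derivative settings.
#' @param mean_bp_scope `"beat"` or `"global"` masking threshold scope.
#' @param refine Iterate the two estimation steps to convergence.
#' @param gap_limit_ms Maximum repairable non-finite gap when reading.
#' @param fit_variant Sigmoid variant fitted to the per-trial table
#'   (`"stimulus"`) or `NULL` to skip fitting.
#' @param seed Seed for any stochastic step (synthesis).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = tempfile("artstiff-run-"),
                            channels = NULL, fs = NULL, baseline = NULL,
                            protocol = NULL, synth = NULL,
                            r2_gate = 0.9, min_mask_samples = 30,
                            window_ms = 21, polyorder = 3,
                            mean_bp_scope = "beat", refine = TRUE,
                            gap_limit_ms = 20, fit_variant = "stimulus",
                            seed = NULL) {
  structure(list(input = input, out_dir = out_dir, channels = channels,
                 fs = fs, baseline = baseline, protocol = protocol,
                 synth = synth, r2_gate = r2_gate,
                 min_mask_samples = min_mask_samples, window_ms = window_ms,
                 polyorder = polyorder, mean_bp_scope = mean_bp_scope,
                 refine = refine, gap_limit_ms = gap_limit_ms,
                 fit_variant = fit_variant, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file whose
#'   keys are the arguments of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path), class = "artstiff_io_error")
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "artstiff_config_error")
  rlang::exec(pipeline_config, !!!vals)
}

#' Run the end-to-end analysis pipeline
#'
#' Reads (or synthesizes) a record, segments it into beats, estimates the
#' per-beat viscoelastic parameters, normalizes the stiffness index against
#' the baseline window, summarizes trials and fits the stimulus-response
#' sigmoid, writing `beats.csv`, `series.csv`, `trials.csv`, `maps.json` and
#' a `run_log.txt` listing every applied setting. The pipeline is pure given
#' the input files, configuration and seed.
#'
#' @param config A [pipeline_config()], or a path to a YAML/JSON config.
#' @return Invisibly, a `pipeline_report` list: output paths, beat counts,
#'   the stiffness series and any fitted maps.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be a pipeline_config or a path to one.",
          class = "artstiff_config_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(sprintf("artstiff run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 "applied settings:")
  flat <- utils::capture.output(utils::str(unclass(config), give.attr = FALSE))
  log_lines <- c(log_lines, flat)

  protocol <- if (!is.null(config$protocol))
    rlang::exec(stim_protocol, !!!config$protocol)
  else if (is.null(config$input)) stim_protocol()
  else NULL

  if (is.null(config$input)) {
    synth_args <- config$synth %||% list()
    if (!is.null(protocol)) synth_args$protocol <- protocol
    if (is.null(synth_args$seed)) synth_args$seed <- config$seed
    if (is.null(synth_args$seed))
      abort("a seed is required for record synthesis.",
            class = "artstiff_config_error")
    synth <- rlang::exec(synthesize_record, !!!synth_args)
    record <- synth$record
    log_lines <- c(log_lines, sprintf("synthesized record: %d beats, seed %s",
                                      nrow(synth$truth), synth_args$seed))
  } else {
    record <- read_waveform_csv(config$input,
                                config = list(channels = config$channels,
                                              fs = config$fs,
                                              gap_limit_ms = config$gap_limit_ms))
    log_lines <- c(log_lines, sprintf("read record: %s (%d samples at %g Hz)",
                                      config$input, nrow(record), record_fs(record)))
  }

  baseline <- config$baseline %||%
    (if (!is.null(protocol)) protocol_baseline_window(protocol) else
       abort("no baseline window given and no protocol to derive one from.",
             class = "artstiff_config_error"))
  if (baseline[1] < 0 || baseline[2] > record_duration(record))
    abort(sprintf("baseline window [%g, %g) lies outside the record (0, %g).",
                  baseline[1], baseline[2], record_duration(record)),
          class = "artstiff_config_error")

  beats <- segment_beats(record)
  estimates <- estimate_record(
    record, beats,
    spec = derivative_spec(config$window_ms, config$polyorder),
    mean_bp_scope = config$mean_bp_scope,
    r2_gate = config$r2_gate, min_mask = config$min_mask_samples,
    refine = config$refine)
  beats_path <- file.path(config$out_dir, "beats.csv")
  write_beat_estimates(estimates, beats_path)
  log_lines <- c(log_lines, sprintf("beats: %d estimated, %d accepted (R^2 gate %g)",
                                    nrow(estimates), sum(estimates$accepted),
                                    config$r2_gate))

  series <- normalize_beta(estimates, baseline)
  series_path <- file.path(config$out_dir, "series.csv")
  readr::write_csv(tibble::as_tibble(series), series_path, progress = FALSE)
  log_lines <- c(log_lines, sprintf("baseline [%g, %g) s: beta max %.6g",
                                    baseline[1], baseline[2],
                                    attr(series, "beta_baseline_max")))

  trials <- NULL; map <- NULL
  trials_path <- NULL; maps_path <- NULL
  if (!is.null(protocol)) {
    trials <- summarize_trials(series, protocol)
    trials_path <- file.path(config$out_dir, "trials.csv")
    readr::write_csv(trials, trials_path, progress = FALSE)
    ok <- is.finite(trials$mean_beta_n)
    if (!is.null(config$fit_variant) &&
        length(unique(trials$level[ok])) >= 3) {
      map <- fit_sigmoid(trials$level[ok], trials$mean_beta_n[ok],
                         variant = config$fit_variant)
      maps_path <- file.path(config$out_dir, "maps.json")
      jsonlite::write_json(list(variant = map$variant, a = map$a, b = map$b,
                                r2 = map$r2, n = map$n,
                                residuals = map$residuals),
                           maps_path, auto_unbox = TRUE, digits = NA)
      log_lines <- c(log_lines,
                     sprintf("sigmoid fit [%s]: a=%.5g b=%.5g R^2=%.4f",
                             map$variant, map$a, map$b, map$r2))
    }
  }
  writeLines(log_lines, logf)
  report <- structure(list(
    paths = purrr::compact(list(beats = beats_path, series = series_path,
                                trials = trials_path, maps = maps_path,
                                log = logf)),
    n_beats = nrow(estimates), n_accepted = sum(estimates$accepted),
    estimates = estimates, series = series, trials = trials, map = map),
    class = "pipeline_report")
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d beats (%d accepted); outputs in %s>\n",
              x$n_beats, x$n_accepted, dirname(x$paths$beats)))
  if (!is.null(x$map)) print(x$map)
  invisible(x)
}
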