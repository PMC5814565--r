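#' Plot a waveform record
#'
#' Facets the ECG, blood-pressure and PPG channels against time.
#'
#' @param object A [waveform_record()].
#' @param window Optional `c(start, end)` in seconds to restrict the view.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.waveform_record <- function(object, window = NULL, ...) {
  df <- tibble::as_tibble(object)[c("time", "ecg", "bp", "ppg")]
  if (!is.null(window))
    df <- dplyr::filter(df, .data$time >= window[1], .data$time < window[2])
  long <- tidyr::pivot_longer(df, c("ecg", "bp", "ppg"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("ecg", "bp", "ppg"),
                         labels = c("ECG (a.u.)", "BP (mmHg)", "PPG (a.u.)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-beat estimates
#'
#' Beta trajectory over time, coloured by gate acceptance.
#'
#' @param object A `beat_estimates` tibble from [estimate_record()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beat_estimates <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.finite(.data$beta))
  ggplot2::ggplot(df, ggplot2::aes(.data$t0, .data$beta,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(hat(beta) ~ "(per PPG unit)"),
                  colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Plot a normalized stiffness series
#'
#' `beta_n` against time with the baseline window shaded.
#'
#' @param object A `stiffness_series` from [normalize_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stiffness_series <- function(object, ...) {
  base <- attr(object, "baseline")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$t0, .data$beta_n)) +
    ggplot2::annotate("rect", xmin = base[["start"]], xmax = base[["end"]],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(beta[n])) +
    ggplot2::theme_minimal()
}

#' Plot a fitted sigmoid map
#'
#' Observed points with the fitted curve.
#'
#' @param object A `sigmoid_map` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_map <- function(object, ...) {
  xr <- range(object$data$x)
  grid <- tibble::tibble(x = seq(xr[1], max(xr[2], xr[1] + 1e-6),
                                 length.out = 200))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (object$variant == "stimulus") "stimulus level S"
          else expression(beta[n]),
      y = if (object$variant == "stimulus") "response" else "eNRS",
      title = sprintf("sigmoid fit [%s]: a=%.3g, b=%.3g, R^2=%.3f",
                      object$variant, object$a, object$b, object$r2)) +
    ggplot2::theme_minimal()
}
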