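#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an airflow trace
#'
#' Airflow against time, optionally overlaying breath-segment boundaries
#' (inspiration onsets solid, expiration onsets dashed) and the pause
#' threshold.
#'
#' @param object An [airflow_trace()].
#' @param segments Optional output of [segment_breaths()].
#' @param flow_threshold Optional pause threshold to draw (mL/s).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot airflow_trace
#' @export
autoplot.airflow_trace <- function(object, segments = NULL,
                                   flow_threshold = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time, .data$flow)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Time (s)", y = "Airflow (mL/s)") +
    ggplot2::theme_minimal()
  if (!is.null(flow_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = flow_threshold,
                                 linetype = "dotted", colour = "red3")
  }
  if (!is.null(segments) && nrow(segments)) {
    rate <- sampling_rate(object)
    t0 <- object$time[1]
    p <- p +
      ggplot2::geom_vline(
        xintercept = t0 + (segments$insp_onset - 1) / rate,
        colour = "steelblue", alpha = 0.6) +
      ggplot2::geom_vline(
        xintercept = t0 + (segments$exp_onset - 1) / rate,
        colour = "steelblue", alpha = 0.6, linetype = "dashed")
  }
  p
}

#' Plot a slice recording or envelope
#'
#' @param object A [slice_trace()].
#' @param bursts Optional burst table from [detect_bursts()].
#' @param ... Unused.
#' @return A ggplot with epoch boundaries and detected burst onsets.
#' @method autoplot slice_trace
#' @export
autoplot.slice_trace <- function(object, bursts = NULL, ...) {
  epochs <- slice_epochs(object)
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = epochs$start_s[-1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Population activity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_point(
      data = bursts,
      ggplot2::aes(.data$peak_s, .data$peak_amplitude),
      colour = "red3", size = 1)
  }
  p
}

#' Plot pause-length densities
#'
#' @param pdf_tbl Output of [pause_pdf()], optionally with an added
#'   grouping column (e.g. `drug`).
#' @param colour Optional name of the grouping column.
#' @return A ggplot step-density plot.
#' @export
plot_pause_pdf <- function(pdf_tbl, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(.data$bin_mid, .data$density)
  } else {
    ggplot2::aes(.data$bin_mid, .data$density,
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(pdf_tbl, aes) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Pause length (ms)", y = "Density (1/ms)") +
    ggplot2::theme_minimal()
}

#' Plot per-animal drug/control ratios
#'
#' One point per animal per metric with the cohort mean, the standard
#' display of a paired crossover comparison.
#'
#' @param ratios Output of [paired_ratios()].
#' @return A ggplot.
#' @export
plot_paired_ratios <- function(ratios) {
  means <- ratios |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(ratio = mean(.data$ratio))
  ggplot2::ggplot(ratios, ggplot2::aes(.data$metric, .data$ratio)) +
    ggplot2::geom_jitter(width = 0.08, colour = "red3", alpha = 0.6,
                         shape = 18, size = 2) +
    ggplot2::geom_point(data = means, shape = 18, size = 4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "morphine / saline ratio") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response curve
#'
#' @param dr Output of [dose_response()] (optionally row-bound across
#'   slices with a `slice` column).
#' @param group Optional grouping column name (e.g. `"slice"` or
#'   genotype).
#' @return A ggplot of normalized rate and amplitude against dose.
#' @export
plot_dose_response <- function(dr, group = NULL) {
  long <- tidyr::pivot_longer(dr, c("rate_norm", "amp_norm"),
                              names_to = "measure", values_to = "value")
  aes <- if (is.null(group)) {
    ggplot2::aes(.data$dose_nm, .data$value)
  } else {
    ggplot2::aes(.data$dose_nm, .data$value, group = .data[[group]])
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "DAMGO (nM)", y = "Fraction of baseline") +
    ggplot2::theme_minimal()
}
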