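#' Plot the four channels of a recording
#'
#' Faceted time-series view of ECG, arterial pressure, respiration and
#' the integrated MSNA neurogram over a time window.
#'
#' @param record An [msna_record()].
#' @param from,to Window bounds in seconds (defaults: first 30 s).
#' @return A ggplot object.
#' @export
plot_record <- function(record, from = NULL, to = NULL) {
  record <- as_record(record)
  d <- record$data
  from <- from %||% min(d$t)
  to <- to %||% min(max(d$t), from + 30)
  d |>
    dplyr::filter(.data$t >= from, .data$t <= to) |>
    tidyr::pivot_longer(-"t", names_to = "channel") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   c("ecg", "pressure", "respiration",
                                     "msna"))) |>
    ggplot2::ggplot(ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MSNA metrics by respiratory phase
#'
#' @param metrics Phase metrics from [phase_metrics()].
#' @return A ggplot object.
#' @export
plot_phase_metrics <- function(metrics) {
  metrics |>
    tidyr::pivot_longer(c("incidence", "frequency", "total_area_per_s",
                          "mean_area_per_s"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$label, .data$value,
                                 fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}

#' @rdname plot_sbrs
#' @exportS3Method ggplot2::autoplot
autoplot.sbrs_result <- function(object, ...) {
  plot_sbrs(object, ...)
}

#' Plot the sympathetic baroreflex fit
#'
#' Burst-occurrence probability per 1-mmHg diastolic-pressure bin (point
#' size = bin count) with the weighted regression line.
#'
#' @param object An `sbrs_result` from [sbrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sbrs <- function(object, ...) {
  fit <- object$occurrence
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(.data$bin_center, .data$p_occurrence)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::labs(x = "diastolic pressure (mmHg)",
                  y = "burst occurrence (%)", size = "beats") +
    ggplot2::theme_minimal()
  if (fit$available) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-breath MSNA against Traube-Hering amplitude
#'
#' @param breath_table Per-breath table from [breath_hemodynamics()].
#' @return A ggplot object.
#' @export
plot_breath_coupling <- function(breath_table) {
  breath_table |>
    dplyr::filter(stats::complete.cases(.data$msna_resp, .data$th)) |>
    ggplot2::ggplot(ggplot2::aes(.data$msna_resp, .data$th)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "respiratory-modulated MSNA (V·s)",
                  y = "Traube–Hering amplitude (mmHg)") +
    ggplot2::theme_minimal()
}
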