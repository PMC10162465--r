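#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Eigenvalue spectrum plot
#'
#' Frequency (Hz) against decay rate for every Koopman eigenvalue, with
#' horizontal guides at the triplet-rate harmonics.
#'
#' @param object A `koopman_decomposition` or `branch_assignment`.
#' @param f_triplet Triplet rate for the harmonic guides (decomposition
#'   method only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.koopman_decomposition <- function(object, f_triplet = 1 / 0.6, ...) {
  tbl <- tidy(object)
  harms <- seq_len(max(1, floor(max(abs(tbl$frequency_hz)) / f_triplet))) * f_triplet
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$decay_rate,
                                    y = abs(.data$frequency_hz))) +
    ggplot2::geom_hline(yintercept = harms, colour = "grey85") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "decay rate (1/s)", y = "|frequency| (Hz)",
                  title = "Koopman eigenvalue spectrum")
}

#' @rdname autoplot.koopman_decomposition
#' @export
autoplot.branch_assignment <- function(object, ...) {
  tbl <- object$table
  tbl$branch[is.na(tbl$branch)] <- "unassigned"
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$decay_rate,
                                    y = abs(.data$frequency_hz),
                                    colour = .data$branch)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "decay rate (1/s)", y = "|frequency| (Hz)",
                  colour = "branch",
                  title = "Stimulus (J1) and perception (J2) branches")
}

#' Slow-feature trace with percept shading
#'
#' @param times Sample times in seconds.
#' @param phi_star Slow-feature series.
#' @param labels Optional [label_triplets()] result used to shade percepts.
#' @return A ggplot object.
#' @export
plot_phi_star <- function(times, phi_star, labels = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(labels)) {
    td <- attr(labels, "triplet_duration")
    shade <- dplyr::filter(tibble::as_tibble(labels), .data$label != "neutral")
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$onset_s + td,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.25
    ) +
      ggplot2::scale_fill_manual(values = c(one_stream = "steelblue",
                                            two_stream = "indianred"))
  }
  p +
    ggplot2::geom_line(data = tibble::tibble(time_s = times,
                                             phi_star = as.numeric(phi_star)),
                       ggplot2::aes(x = .data$time_s, y = .data$phi_star)) +
    ggplot2::labs(x = "time (s)", y = "phi*", fill = "percept",
                  title = "Slow percept-tracking feature")
}

#' Predictor trace with predicted windows and button presses
#'
#' @param times Sample times in seconds.
#' @param predictor Switch-predictor series in `[0, 1]`.
#' @param windows A [predict_switches()] result.
#' @param button_times Optional reported press times.
#' @return A ggplot object.
#' @export
plot_switch_prediction <- function(times, predictor, windows,
                                   button_times = NULL) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = tibble::as_tibble(windows),
      ggplot2::aes(xmin = .data$win_start, xmax = .data$win_end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_line(
      data = tibble::tibble(time_s = times, p = predictor),
      ggplot2::aes(x = .data$time_s, y = .data$p)
    ) +
    ggplot2::geom_hline(yintercept = attr(windows, "threshold"),
                        linetype = "dashed")
  if (!is.null(button_times) && length(button_times)) {
    p <- p + ggplot2::geom_vline(xintercept = button_times, colour = "indianred")
  }
  p + ggplot2::labs(x = "time (s)", y = "predictor",
                    title = "Phase-based switch predictor")
}
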