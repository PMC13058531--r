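#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none reference
#' policies across threshold probabilities.
#'
#' @param object A `sepsis_decision_curve` from [decision_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sepsis_decision_curve <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("net_benefit", "treat_all", "treat_none"),
                        names_to = "policy", values_to = "nb")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                   colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, attr(object, "prevalence") * 1.2)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot experiment results across horizons
#'
#' One panel per metric: point estimate with bootstrap CI ribbon against
#' the prediction horizon, colored by strategy, line type by onset
#' matching.
#'
#' @param object A `sepsis_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sepsis_experiment <- function(object, ...) {
  df <- object$results |>
    dplyr::mutate(matching = ifelse(.data$matching, "matched", "unmatched"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$horizon, y = .data$value,
                                   colour = .data$strategy,
                                   linetype = .data$matching)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                                      fill = .data$strategy), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Prediction horizon (h)", y = "Metric value") +
    ggplot2::theme_minimal()
}

#' Plot alarm rates
#'
#' @param summary Output of [alarm_rates()].
#' @return A ggplot object comparing raw and silenced alarm rates per group.
#' @export
plot_alarm_rates <- function(summary) {
  df <- summary |>
    tidyr::pivot_longer(c("rate", "rate_silenced"), names_to = "kind",
                        values_to = "alarms_per_hour") |>
    dplyr::mutate(kind = ifelse(.data$kind == "rate", "raw", "silenced"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$alarms_per_hour,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Alarms per patient-hour", fill = NULL) +
    ggplot2::theme_minimal()
}
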