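#' Plot the daily stress curve
#'
#' Mean stress fraction by clock hour with a standard-error ribbon — the
#' view in which the three daily stress waves (first work hour, early
#' afternoon, evening) are visible.
#'
#' @param curve output of [daily_stress_curve()]
#' @return a ggplot
#' @export
plot_stress_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$bin_min / 60,
                                      y = 100 * .data$mean_fraction)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = 100 * (.data$mean_fraction - .data$se_fraction),
      ymax = 100 * (.data$mean_fraction + .data$se_fraction)),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "Hour of day", y = "Stress duration (% of valid time)",
                  title = "Cohort stress duration by hour") +
    ggplot2::theme_minimal()
}

#' Plot temporal work patterns by group
#'
#' Mean inbox and other-EHR minutes per clock hour for each work-pattern
#' group, the standard view of how the groups distribute EHR work over
#' the day.
#'
#' @param usage output of [hourly_usage()]
#' @param assignments tibble `physician_id`, `group`
#' @return a ggplot
#' @export
plot_temporal_patterns <- function(usage, assignments) {
  dat <- usage |>
    inner_join(assignments, by = "physician_id") |>
    mutate(hour = .min_of_day(.data$bin_start) / 60) |>
    group_by(.data$group, .data$hour) |>
    summarise(inbox = mean(.data$minutes_inbox),
              other = mean(.data$minutes_ehr - .data$minutes_inbox),
              .groups = "drop") |>
    pivot_longer(c("inbox", "other"), names_to = "activity",
                 values_to = "minutes")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hour, y = .data$minutes,
                                    fill = .data$activity)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::facet_wrap(~ .data$group, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "Hour of day", y = "Mean minutes per hour",
                  fill = NULL, title = "Temporal patterns of EHR work") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stress_glmm <- function(object, ...) {
  dat <- object$coefficients |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term,
                                                       .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = "Coefficient (log rate scale)", y = NULL,
                  title = "Stress association model fixed effects") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
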