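#' Plot the piecewise utility functions
#'
#' Draws the utility of positive and negative predictions against time
#' relative to sepsis onset for a septic patient, the visual definition of
#' the scoring metric.
#'
#' @param object A [utility_params()] object.
#' @param t_sepsis Example onset hour used for the x axis (default 48).
#' @param hours Record length to draw (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.utility_params <- function(object, t_sepsis = 48, hours = 60, ...) {
  h <- seq(0, hours - 1, by = 0.25)
  df <- dplyr::bind_rows(
    tibble(hour = h, prediction = "positive",
           utility = prediction_utility(TRUE, t_sepsis, h, 1, object)),
    tibble(hour = h, prediction = "negative",
           utility = prediction_utility(TRUE, t_sepsis, h, 0, object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$utility,
                                   colour = .data$prediction)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = t_sepsis, linetype = 2) +
    ggplot2::labs(x = "ICU hour", y = "utility",
                  title = "Per-window utility around sepsis onset",
                  subtitle = sprintf("onset at hour %g", t_sepsis)) +
    ggplot2::theme_minimal()
}

#' Plot a per-variable distribution-shift table
#'
#' @param object A [shift_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object (Jensen-Shannon divergence per variable).
#' @export
plot_shift_report <- function(object, ...) {
  df <- dplyr::filter(object, !.data$flagged)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$jsd),
    y = .data$jsd, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Jensen-Shannon divergence (base 2)",
                  title = "Distribution shift between cohorts") +
    ggplot2::theme_minimal()
}

#' Plot cohort measurement densities
#'
#' @param object The `overall` tibble from [measurement_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_measurement_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$variable, y = .data$density, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of non-missing hourly cells",
                  title = "Measurement density by variable") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
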