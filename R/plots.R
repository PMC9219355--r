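#' Plot feasibility summary rows
#'
#' Dot-and-interval plot of the feasibility percentages with their 99%
#' Clopper-Pearson intervals, one panel per break policy, colored by
#' supervision level.
#'
#' @param object A [summarize_feasibility()] result (rows from several
#'   policies may be bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot break_summary
#' @export
autoplot.break_summary <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$facility, y = .data$pct,
                                   color = .data$measure)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$window)) +
    ggplot2::labs(x = NULL, y = "Cases with a feasible break (%)",
                  color = "Rooms supervised") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the facility covariate association
#'
#' Single-room feasibility percentage against the facility's percentage of
#' cases at least as long as the break plus lead-in, one point per facility
#' and window, with the identity line (feasibility can never exceed the
#' retrospective percentage).
#'
#' @param object A [facility_covariate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot facility_covariate
#' @export
autoplot.facility_covariate <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = factor(.data$duration_min),
                               shape = .data$facility)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = "Cases at least break + lead-in long (%)",
      y = "Single-room break feasibility (%)",
      color = "Break (min)", shape = "Facility") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
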