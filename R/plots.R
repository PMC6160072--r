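#' Plot a simulated trajectory
#'
#' Faceted time-series view of the three stocks (and optionally the derived
#' memory-time and let-it-go series) for one or more simulated individuals.
#'
#' @param trajectory Long trajectory tibble from [simulate_profiles()].
#' @param vars Which series to show.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory,
                            vars = c("D", "R", "S")) {
  long <- tidyr::pivot_longer(trajectory, dplyr::all_of(vars),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     group = .data$id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (months)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scenario ensemble
#'
#' Mean depressive-symptom trajectory with the 75% envelope (12.5th to
#' 87.5th percentile across replicates) and the clinical threshold at 16.
#'
#' @param object A `rumidyn_scenario` tibble from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rumidyn_scenario <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$month, .data$mean_D)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 16, linetype = 2) +
    ggplot2::labs(x = "time (months)", y = "depressive symptoms (CDI)")
}

#' Plot a sensitivity grid
#'
#' Tile/contour view of mean terminal depressive symptoms over the initial
#' rumination by stressor-inflow grid, with the clinical threshold contour
#' at 16.
#'
#' @param object A `rumidyn_sensitivity` tibble from [sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rumidyn_sensitivity <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$R0, .data$inflow)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mean_D)) +
    ggplot2::labs(x = "initial rumination", y = "ongoing stressors (events/month)",
                  fill = "D at horizon")
  if (length(unique(object$R0)) > 2 && length(unique(object$inflow)) > 2) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$mean_D),
                                   breaks = 16, colour = "black")
  }
  p
}
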