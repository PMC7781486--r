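# ggplot2 views of the result objects.

#' Plot a cohort score distribution
#'
#' Histogram of the per-circuit ensemble-mean adapted metric with dashed
#' lines at the cohort mean and one standard deviation above it (the poor-
#' performer threshold).
#'
#' @param object A `blade_cohort`.
#' @param binwidth Histogram bin width in degrees.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blade_cohort <- function(object, binwidth = 0.25, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$mean_theta_bar)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mu, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mu + object$sigma, linetype = "dotted") +
    ggplot2::labs(x = "ensemble-mean adapted angular metric (deg)", y = "circuits")
}

#' Plot sorted cohort scores
#'
#' Per-circuit mean adapted metric in ascending order, with the cohort mean
#' and mean-plus-one-sd reference lines; circuits above the upper line are
#' the poor performers.
#'
#' @param cohort A `blade_cohort`.
#' @return A ggplot.
#' @export
plot_sorted_scores <- function(cohort) {
  df <- dplyr::arrange(cohort$scores, .data$mean_theta_bar)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mean_theta_bar)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_poor), size = 1) +
    ggplot2::geom_hline(yintercept = cohort$mu, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cohort$mu + cohort$sigma, linetype = "dotted") +
    ggplot2::labs(x = "circuit (sorted)", y = "mean adapted metric (deg)",
                  colour = "poor") +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a calibration convergence trace
#'
#' @param object A `blade_calibration`.
#' @param ... Unused.
#' @return A ggplot of best and population-mean objective per generation.
#' @export
autoplot.blade_calibration <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("best", "mean"),
                              names_to = "series", values_to = "E")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$E,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "objective E (deg)", colour = NULL)
}

#' Plot a ratio scan
#'
#' Mean adapted metric (with one-sd ribbons) against the recombinase
#' expression scale, one line per circuit; the x axis is reversed so
#' performance degrades left to right as expression falls.
#'
#' @param object A `blade_ratio_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blade_ratio_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$circuit <- factor(df$circuit_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$mean_theta_bar,
                                   colour = .data$circuit, group = .data$circuit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "recombinase expression scale", y = "mean adapted metric (deg)",
                  colour = "circuit")
}
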