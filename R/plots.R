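#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep result
#'
#' Mean classification score per method against the swept parameter (noise
#' standard deviation or bin size), with one line per method.
#'
#' @param object A `sweep_result` from [noise_sweep()] or [binning_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  axis <- attr(object, "axis")
  means <- glance(object)
  ggplot2::ggplot(means, ggplot2::aes(x = .data[[axis]], y = .data$mean_score,
                                      colour = .data$method,
                                      shape = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (axis == "sigma") "noise standard deviation" else
                    "bin size",
                  y = "mean classification score (%)", colour = NULL,
                  shape = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a longitudinal link-density trajectory
#'
#' @param object A `trajectory_result` from [track_evolution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$timepoint, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "timepoint",
                  y = sprintf("link density (threshold %g)",
                              attr(object, "threshold_used"))) +
    ggplot2::theme_minimal()
}

#' Feature-space plot of a cohort
#'
#' Scatter of subjects in the plane of two network features, coloured by
#' class — the view in which a separable cohort shows two distinct clouds.
#'
#' @param features A tibble from [feature_table()].
#' @param x,y Feature column names (defaults: density and efficiency).
#' @return A ggplot object.
#' @export
plot_feature_space <- function(features, x = "density", y = "efficiency") {
  ggplot2::ggplot(features, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                         colour = .data$label,
                                         shape = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
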