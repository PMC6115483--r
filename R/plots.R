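#' Plot a sweep: mean ratio vs condition value
#'
#' Line through the grid means with error bars of one between-replicate
#' standard deviation, the layout used for the load and strength figures.
#'
#' @param object a `mu_sweep` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mu_sweep <- function(object, ...) {
  lab <- sweep_axis_label(object$condition[1])
  ok <- object[object$feasible, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$value, y = .data$mean_ratio)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ratio - .data$sd_ratio,
                   ymax = .data$mean_ratio + .data$sd_ratio),
      width = 0, colour = "grey55") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab,
                  y = "mean MU relaxation/contraction time ratio") +
    ggplot2::theme_minimal()
}

sweep_axis_label <- function(condition) {
  switch(condition,
         load_fraction = "load (fraction of maximum muscle strength)",
         strength_multiplier = "maximum strength (multiple of reference)",
         condition)
}

#' Plot the uniform vs small-unit-biased comparison
#'
#' @param object a `mu_bias_comparison` tibble.
#' @param ... unused.
#' @return A ggplot object with one curve per recruitment policy.
#' @export
autoplot.mu_bias_comparison <- function(object, ...) {
  lab <- sweep_axis_label(object$condition[1])
  ok <- object[object$feasible, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$value, y = .data$mean_ratio,
                                   colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(uniform = "#3366bb", small_biased = "#cc3333")) +
    ggplot2::labs(x = lab,
                  y = "mean MU relaxation/contraction time ratio",
                  colour = "recruitment") +
    ggplot2::theme_minimal()
}

#' Plot per-unit outcomes of a rotation run
#'
#' Per-unit relaxation/contraction ratio against twitch force (log x axis);
#' under the uniform policy the points scatter around a flat line, under the
#' small-unit-biased policy small units sit below large ones.
#'
#' @param object a `mu_rotation` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mu_rotation <- function(object, ...) {
  units <- tidy(object)
  units <- units[is.finite(units$ratio), , drop = FALSE]
  ggplot2::ggplot(units, ggplot2::aes(x = .data$twitch_force,
                                      y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_ratio, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "twitch force (arbitrary units, log scale)",
                  y = "unit relaxation/contraction time ratio") +
    ggplot2::theme_minimal()
}

#' Plot a chronicity trajectory
#'
#' Three-curve layout: total muscle strength, the declining energy-crisis
#' threshold load, and the fluctuating applied load, with pain episodes
#' (applied load above threshold) marked along the time axis.
#'
#' @param object a `mu_chronicity` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mu_chronicity <- function(object, ...) {
  long <- tibble::tibble(
    time = rep(object$time, 3),
    value = c(object$strength, object$threshold_load, object$applied_load),
    series = rep(c("muscle strength", "threshold load", "applied load"),
                 each = nrow(object))
  )
  episodes <- object[object$episode, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = episodes,
                        ggplot2::aes(x = .data$time, y = .data$applied_load),
                        inherit.aes = FALSE, shape = 25, fill = "#cc3333",
                        colour = "#cc3333", size = 1.8) +
    ggplot2::scale_colour_manual(
      values = c("muscle strength" = "#339944",
                 "threshold load" = "#cc3333",
                 "applied load" = "#3366bb")) +
    ggplot2::labs(x = "time (arbitrary units)", y = "force (arbitrary units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
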