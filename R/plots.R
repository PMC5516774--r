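#' Plot a simulated trajectory
#'
#' One panel per model variable (plus total viability), drawn against time.
#'
#' @param object A `cartox_trajectory` from [simulate_cartox()].
#' @param vars Variables to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cartox_trajectory <- function(object,
                                       vars = c("M", "D", "R", "E", "U",
                                                "viability"), ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("time_h", vars)],
                              cols = -"time_h", names_to = "variable")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "relative level") +
    ggplot2::theme_minimal()
}

#' Plot a calibration against its observations
#'
#' Observed means with +/- SD error bars and the fitted model curves, one
#' facet per observation stream.
#'
#' @param object A `cartox_fit`.
#' @param observations The observation tibble the fit was run on.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cartox_fit <- function(object, observations, ...) {
  obs <- validate_observations(observations)
  horizon <- max(obs$time_h)
  traj <- simulate_impact(object$parameters, object$initial_ros,
                          times = seq(0, horizon, length.out = 400))
  curves <- tibble(
    time_h = rep(traj$time_h, 3),
    stream = rep(c("viability", "atp", "gag"), each = nrow(traj)),
    value = c(traj$viability, traj$E, traj$U)
  ) |> filter(.data$stream %in% unique(obs$stream))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$value),
                       colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.3) +
    ggplot2::facet_wrap(~stream, scales = "free_x") +
    ggplot2::labs(x = "time (h)", y = "fraction of control") +
    ggplot2::theme_minimal()
}

#' Plot relative sensitivity trajectories
#'
#' @param object A `cartox_sensitivity` tibble (one target) or the
#'   `trajectories` element of a [sensitivity_report()].
#' @param measure `"relative"` or `"raw"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cartox_sensitivity <- function(object, measure = c("relative",
                                                            "raw"), ...) {
  measure <- match.arg(measure)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                   y = .data[[measure]],
                                   colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = paste(measure, "sensitivity")) +
    ggplot2::theme_minimal()
}
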