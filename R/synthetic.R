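#' Observation designs matching the impact experiments
#'
#' The sampling scheme of the drop-tower study: viability at 9 time points
#' over 72 h, and for the 7 J/cm^2 energy additionally ATP at 24 and 48 h
#' and GAG at 7 and 14 d (168 and 336 h), each with the per-point standard
#' deviation reported in the experiments. Used by
#' [simulate_observations()] to generate synthetic data with the study's
#' statistical structure.
#'
#' @param impact `"7J"` or `"14J"`.
#' @return A tibble with columns `stream`, `time_h`, `sd` (13 rows for
#'   `"7J"`, 9 for `"14J"`).
#' @examples
#' observation_design("7J")
#' @export
observation_design <- function(impact = c("7J", "14J")) {
  obs <- impact_observations(impact)
  design <- obs[, c("stream", "time_h", "sd")]
  attr(design, "impact") <- attr(obs, "impact")
  design
}

#' Generate synthetic observations from a model trajectory
#'
#' Simulates the model from the impact initial state `(1, 0, R(0), 1, 1)`
#' and draws, for every design row, an observed mean from a Gaussian
#' centred on the model value with the design's standard deviation,
#' clamped at zero (no negative concentrations or viabilities).
#' Deterministic for a given seed.
#'
#' @param params A [cartox_params()] object.
#' @param initial_ros Initial relative ROS `R(0)` of the generating
#'   trajectory.
#' @param design A design tibble (`stream`, `time_h`, `sd`), e.g. from
#'   [observation_design()].
#' @param seed Integer RNG seed.
#' @param rtol,atol Integration tolerances.
#' @return An observation tibble (`stream`, `time_h`, `mean`, `sd`)
#'   compatible with the fitting functions, with the generating `seed` and
#'   `initial_ros` stored as attributes.
#' @examples
#' simulate_observations(initial_ros = 1.05,
#'                       design = observation_design("7J"), seed = 1)
#' @export
simulate_observations <- function(params = cartox_params(),
                                  initial_ros = 1.0202,
                                  design = observation_design("7J"),
                                  seed = 0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(c("stream", "time_h", "sd") %in% names(design)),
            nrow(design) > 0)
  if (any(design$sd < 0)) abort("design sds must be >= 0")
  truth <- predict_observations(
    mutate(as_tibble(design), mean = 0), params, initial_ros,
    rtol = rtol, atol = atol)
  set.seed(as.integer(seed))
  noisy <- pmax(0, rnorm(nrow(truth), mean = truth$.fitted, sd = design$sd))
  out <- tibble(stream = design$stream, time_h = design$time_h,
                mean = noisy, sd = design$sd)
  out <- validate_observations(out)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "initial_ros") <- initial_ros
  out
}
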