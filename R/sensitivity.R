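sensitivity_param_targets <- c("k_S", "delta_D", "delta_R", "s_C", "k_E",
                               "lambda_E", "k_U", "lambda_U")
sensitivity_ic_targets <- c("M(0)", "D(0)", "R(0)", "E(0)", "U(0)")

#' All forward-sensitivity targets
#'
#' The eight analysed rate/shape parameters and the five initial conditions.
#' `epsilon`, `alpha` and `k_D` are structural constants and are not part of
#' the analysis.
#'
#' @return Character vector of length 13.
#' @export
sensitivity_targets <- function() {
  c(sensitivity_param_targets, sensitivity_ic_targets)
}

#' Forward local sensitivity of the model to one target
#'
#' Solves the forward sensitivity system `dS/dt = J S + F` jointly with the
#' model, where `J` is the analytic state Jacobian ([model_jacobian()]) and
#' `F` the partial derivative of the right-hand side with respect to the
#' target. For a parameter target the sensitivity starts at zero and `F` is
#' the corresponding forcing vector (with the constraint-derived parameters
#' co-varying: `alpha_M` follows `delta_R`, `delta_E` follows `k_E` and
#' `lambda_E`); for an initial-condition target `F = 0` and the sensitivity
#' starts at the indicator vector of that variable.
#'
#' The relative measure `S(t) / var(t)` is reported alongside the raw
#' sensitivity and is `NA` where `|var| < 1e-8` (for example the sensitivity
#' of `D` to `D(0)` at `t = 0`, where `D = 0`).
#'
#' @param params A [cartox_params()] object.
#' @param initial Length-5 initial state; defaults to the 7 J/cm^2 scenario.
#' @param target One of [sensitivity_targets()].
#' @param times Output grid in hours, starting at 0.
#' @param rtol,atol Integration tolerances (tight by default; the
#'   sensitivities are validated against finite differences at the 0.1%
#'   level).
#' @return A tibble of class `cartox_sensitivity` with columns `target`,
#'   `time_h`, `variable`, `value` (the state), `raw` and `relative`.
#' @examples
#' sensitivity_trajectories(target = "R(0)", times = seq(0, 24, 1))
#' @export
sensitivity_trajectories <- function(params = cartox_params(),
                                     initial = c(1, 0, 1.0202, 1, 1),
                                     target = "R(0)",
                                     times = seq(0, 72, 0.5),
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "cartox_params"))
  if (!target %in% sensitivity_targets()) {
    abort(sprintf("unknown sensitivity target `%s`", target))
  }
  y0 <- as_state(initial)
  is_ic <- target %in% sensitivity_ic_targets
  s0 <- if (is_ic) {
    as.numeric(sensitivity_ic_targets == target)
  } else {
    numeric(5)
  }
  aug_rhs <- function(t, y, p) {
    state <- y[1:5]
    dstate <- cartox_rhs(t, state, p)[[1]]
    J <- model_jacobian(state, p)
    FF <- if (is_ic) numeric(5) else param_partials(state, p, target)
    list(c(dstate, J %*% y[6:10] + FF))
  }
  sol <- deSolve::ode(y = c(y0, s0), times = times, func = aug_rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  m <- unclass(sol)
  if (nrow(m) < length(times) || any(!is.finite(m))) {
    abort(sprintf("sensitivity integration failed after t = %g h",
                  m[nrow(m), 1]))
  }
  value <- as.vector(m[, 2:6])
  raw <- as.vector(m[, 7:11])
  out <- tibble(target = target,
                time_h = rep(m[, 1], times = 5),
                variable = rep(state_names, each = nrow(m)),
                value = value, raw = raw,
                relative = ifelse(abs(value) < 1e-8, NA_real_, raw / value)) |>
    arrange(.data$time_h, match(.data$variable, state_names))
  class(out) <- c("cartox_sensitivity", class(out))
  out
}

#' Forward-sensitivity report over all targets
#'
#' Runs [sensitivity_trajectories()] for every requested target and ranks
#' targets by the largest relative-sensitivity magnitude attained over time
#' and variables.
#'
#' @inheritParams sensitivity_trajectories
#' @param targets Targets to analyse (default: all 13).
#' @return A list of class `cartox_sensitivity_report` with elements
#'   `trajectories` (one long tibble) and `summary` (one row per target with
#'   `max_abs_relative`, ranked).
#' @export
sensitivity_report <- function(params = cartox_params(),
                               initial = c(1, 0, 1.0202, 1, 1),
                               times = seq(0, 72, 0.5),
                               targets = sensitivity_targets(),
                               rtol = 1e-10, atol = 1e-12) {
  trajs <- map(targets, function(tg) {
    sensitivity_trajectories(params, initial, tg, times, rtol, atol)
  })
  all <- bind_rows(trajs)
  summ <- all |>
    group_by(.data$target) |>
    summarise(max_abs_relative = if (all(is.na(.data$relative))) NA_real_
              else max(abs(.data$relative), na.rm = TRUE),
              max_abs_raw = max(abs(.data$raw)),
              .groups = "drop") |>
    mutate(type = ifelse(.data$target %in% sensitivity_ic_targets,
                         "initial_condition", "parameter")) |>
    arrange(dplyr::desc(.data$max_abs_relative))
  structure(list(trajectories = all, summary = summ),
            class = "cartox_sensitivity_report")
}

#' @export
print.cartox_sensitivity_report <- function(x, ...) {
  cat("<cartox_sensitivity_report>\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Ranked sensitivity summary
#'
#' @param report A `cartox_sensitivity_report`.
#' @return The `summary` tibble, targets ranked by `max_abs_relative`.
#' @export
sensitivity_summary <- function(report) {
  stopifnot(inherits(report, "cartox_sensitivity_report"))
  report$summary
}
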