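#' Integrate the oxidative-stress model over a time grid
#'
#' Solves the five-variable system with a stiff-capable variable-order
#' integrator ([deSolve::lsoda()]) and returns the trajectory as a tibble,
#' one row per requested time, together with the two derived observables:
#' total viability `M + D` and the ROS-per-cell ratio
#' `R / (M + D + epsilon)`.
#'
#' @param params A [cartox_params()] object.
#' @param initial Length-5 nonnegative initial state `(M, D, R, E, U)`.
#' @param times Strictly increasing time grid in hours, starting at 0.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param engine `"compiled"` (default) uses the C implementation of the
#'   right-hand side; `"r"` uses [cartox_rhs()]. Both give identical results
#'   and a test asserts as much; the compiled path is what the fitting inner
#'   loop relies on.
#' @return A tibble of class `cartox_trajectory` with columns `time_h`,
#'   `M`, `D`, `R`, `E`, `U`, `viability`, `ros_per_cell`, and a
#'   `solver_report` attribute (method, tolerances, step statistics).
#' @examples
#' traj <- simulate_cartox(times = seq(0, 72, 1))
#' traj[1, ]
#' @export
simulate_cartox <- function(params = cartox_params(),
                            initial = c(1, 0, 1, 1, 1),
                            times = seq(0, 72, 0.1),
                            rtol = 1e-8, atol = 1e-10,
                            engine = c("compiled", "r")) {
  stopifnot(inherits(params, "cartox_params"))
  engine <- match.arg(engine)
  y0 <- as_state(initial)
  if (any(y0 < 0)) abort("initial state must be nonnegative")
  if (length(times) < 2L || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with at least two points")
  }
  if (times[1] != 0) abort("`times` must start at 0")

  sol <- if (engine == "compiled") {
    deSolve::ode(y = y0, times = times, func = "cartox_derivs",
                 parms = param_vector(params), dllname = "cartox",
                 initfunc = "cartox_initmod", method = "lsoda",
                 rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times, func = cartox_rhs, parms = params,
                 method = "lsoda", rtol = rtol, atol = atol)
  }
  m <- unclass(sol)
  if (nrow(m) < length(times) || any(!is.finite(m))) {
    abort(sprintf(
      "integration failed after t = %g h (step-size collapse or non-finite state)",
      m[nrow(m), 1]))
  }
  istate <- attr(sol, "istate")
  out <- tibble(
    time_h = m[, 1],
    M = m[, 2], D = m[, 3], R = m[, 4], E = m[, 5], U = m[, 6],
    viability = m[, 2] + m[, 3],
    ros_per_cell = m[, 4] / (m[, 2] + m[, 3] + params$epsilon)
  )
  attr(out, "solver_report") <- list(
    method = "lsoda", engine = engine, rtol = rtol, atol = atol,
    n_steps = if (length(istate) >= 2) unname(istate[2]) else NA_integer_,
    n_rhs_evals = if (length(istate) >= 3) unname(istate[3]) else NA_integer_,
    n_jac_evals = if (length(istate) >= 14) unname(istate[14]) else NA_integer_
  )
  attr(out, "params") <- params
  class(out) <- c("cartox_trajectory", class(out))
  out
}

#' Simulate the post-impact scenario
#'
#' Convenience wrapper around [simulate_cartox()] for the standard impact
#' experiment: all cells functional, ATP and GAG at control, and an initial
#' ROS burst `R(0)` set by the impact energy.
#'
#' @param params A [cartox_params()] object.
#' @param initial_ros Initial relative ROS concentration `R(0)`.
#' @param times Time grid in hours (default: 0-72 h at 0.1 h resolution).
#' @param ... Passed on to [simulate_cartox()].
#' @return A `cartox_trajectory` tibble.
#' @examples
#' simulate_impact(initial_ros = 1.0202, times = seq(0, 72, 1))
#' @export
simulate_impact <- function(params = cartox_params(), initial_ros = 1.0202,
                            times = seq(0, 72, 0.1), ...) {
  if (!is.numeric(initial_ros) || length(initial_ros) != 1L ||
      !is.finite(initial_ros) || initial_ros < 0) {
    abort("`initial_ros` must be a single nonnegative number")
  }
  simulate_cartox(params, c(1, 0, initial_ros, 1, 1), times, ...)
}

#' Derived observables of a trajectory
#'
#' `viability()` returns the total live-cell fraction `M + D`;
#' `ros_per_cell()` returns `R / (M + D + epsilon)` with the same division
#' guard `epsilon` used inside the model equations.
#'
#' @param traj A data frame with columns `M`, `D` (and `R` for
#'   `ros_per_cell()`), typically a `cartox_trajectory`.
#' @param epsilon Division guard; defaults to the value stored with the
#'   trajectory, or `1e-4`.
#' @return A numeric vector aligned with the rows of `traj`.
#' @export
viability <- function(traj) {
  stopifnot(all(c("M", "D") %in% names(traj)))
  traj$M + traj$D
}

#' @rdname viability
#' @export
ros_per_cell <- function(traj, epsilon = NULL) {
  stopifnot(all(c("M", "D", "R") %in% names(traj)))
  if (is.null(epsilon)) {
    p <- attr(traj, "params")
    epsilon <- if (!is.null(p)) p$epsilon else 1e-4
  }
  traj$R / (traj$M + traj$D + epsilon)
}

#' Write a trajectory to CSV
#'
#' Columns `time_h, M, D, R, E, U, viability, ros_per_cell`, comma-separated,
#' `.` decimal.
#'
#' @param traj A `cartox_trajectory` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_h", "M", "D", "R", "E", "U", "viability", "ros_per_cell")
  stopifnot(all(cols %in% names(traj)))
  readr::write_csv(as_tibble(traj)[, cols], path)
  invisible(path)
}
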