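#' Model predictions at the observation design points
#'
#' Simulates from the standard impact initial state `(1, 0, R(0), 1, 1)` and
#' evaluates, for each observation record, the matching model observable:
#' `M + D` for `viability`, `E` for `atp`, `U` for `gag`.
#'
#' @param observations Observation tibble (see [impact_observations()]).
#' @param params A [cartox_params()] object.
#' @param initial_ros Initial relative ROS `R(0)`.
#' @param rtol,atol Integration tolerances.
#' @param engine Right-hand-side implementation, see [simulate_cartox()].
#' @return The observation tibble with a `.fitted` column appended.
#' @export
predict_observations <- function(observations, params = cartox_params(),
                                 initial_ros = 1.0202,
                                 rtol = 1e-8, atol = 1e-10,
                                 engine = "compiled") {
  obs <- validate_observations(observations)
  times <- sort(unique(c(0, obs$time_h)))
  traj <- simulate_impact(params, initial_ros, times, rtol = rtol,
                          atol = atol, engine = engine)
  i <- match(obs$time_h, traj$time_h)
  obs$.fitted <- dplyr::case_when(
    obs$stream == "viability" ~ traj$viability[i],
    obs$stream == "atp" ~ traj$E[i],
    TRUE ~ traj$U[i]
  )
  obs
}

#' Pooled RMSE between model and observations
#'
#' The calibration objective: root of the mean squared residual
#' (prediction minus observed mean), pooled with equal weight over all
#' records in the observation set, on the fraction-of-control scale.
#'
#' @inheritParams predict_observations
#' @return A single nonnegative number.
#' @examples
#' rmse_objective(impact_observations("7J"), cartox_params(), 1.0202)
#' @export
rmse_objective <- function(observations, params = cartox_params(),
                           initial_ros = 1.0202, rtol = 1e-8, atol = 1e-10,
                           engine = "compiled") {
  if (nrow(observations) == 0L) abort("observations must be non-empty")
  pred <- predict_observations(observations, params, initial_ros,
                               rtol = rtol, atol = atol, engine = engine)
  sqrt(mean((pred$.fitted - pred$mean)^2))
}

# fast unvalidated objective used inside the optimizer loops; returns Inf on
# solver failure so the swarm treats the point as infeasible
make_rmse_fn <- function(observations, rtol, atol) {
  obs <- validate_observations(observations)
  times <- sort(unique(c(0, obs$time_h)))
  idx <- match(obs$time_h, times)
  is_v <- obs$stream == "viability"
  is_a <- obs$stream == "atp"
  target <- obs$mean
  function(params, initial_ros) {
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = c(1, 0, initial_ros, 1, 1), times = times,
        func = "cartox_derivs", parms = param_vector(params),
        dllname = "cartox", initfunc = "cartox_initmod",
        method = "lsoda", rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(sol)) return(Inf)
    m <- unclass(sol)
    if (nrow(m) < length(times) || any(!is.finite(m))) return(Inf)
    fitted <- ifelse(is_v, m[idx, 2] + m[idx, 3],
                     ifelse(is_a, m[idx, 5], m[idx, 6]))
    sqrt(mean((fitted - target)^2))
  }
}

default_fit_bounds <- function(free) {
  all_bounds <- list(
    k_S = c(1e-3, 20), delta_D = c(1e-3, 20), delta_R = c(1e-3, 20),
    s_C = c(1e-3, 20), k_E = c(1e-3, 20), k_U = c(1e-3, 20),
    lambda_E = c(1e-3, 5), lambda_U = c(1e-3, 5)
  )
  missing <- setdiff(free, names(all_bounds))
  if (length(missing)) {
    abort(sprintf("no default bounds for: %s", paste(missing, collapse = ", ")))
  }
  all_bounds[free]
}

new_cartox_fit <- function(parameters, initial_ros, objective_value, report) {
  structure(list(parameters = parameters, initial_ros = initial_ros,
                 objective_value = objective_value,
                 optimizer_report = report),
            class = "cartox_fit")
}

#' Calibrate the model to an observation set
#'
#' Minimizes the pooled [rmse_objective()] over the chosen free parameters
#' and the initial ROS burst `R(0)` with a seeded multi-start particle
#' swarm ([ps_optimize()]) followed by a local polish. The constraint-derived
#' parameters (`alpha_M`, `R_0`, `delta_E`) are recomputed inside the
#' objective, so every candidate respects the homeostasis relationships.
#' `epsilon`, `alpha`, `k_D` and (by default) `k_U` stay fixed at their
#' values in `params`; add `"k_U"` to `free` to release it.
#'
#' @param observations Observation tibble.
#' @param params Baseline [cartox_params()] supplying the fixed parameters.
#' @param free Character vector of free parameter names.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults bracket the published values comfortably (rates in
#'   \[1e-3, 20\], shape constants in \[1e-3, 5\]).
#' @param ros_bounds Search interval for `R(0)`.
#' @param seed Integer seed; the whole fit is reproducible given the seed.
#' @param control A [swarm_control()]; the default uses 5 restarts of a
#'   60-particle, 200-iteration swarm with polish.
#' @param rtol,atol Integration tolerances for the objective.
#' @return A `cartox_fit` object: completed parameters, fitted `R(0)`,
#'   objective value, and an optimizer report (seed, bounds, restart table,
#'   convergence flag). Methods: [tidy()], [glance()], `print()`,
#'   [autoplot()].
#' @examples
#' \donttest{
#' obs <- impact_observations("7J")
#' fit <- fit_impact(obs, seed = 0,
#'                   control = swarm_control(n_particles = 20, iters = 30))
#' glance(fit)
#' }
#' @export
fit_impact <- function(observations, params = cartox_params(),
                       free = c("k_S", "delta_D", "delta_R", "s_C", "k_E",
                                "lambda_E", "lambda_U"),
                       bounds = NULL, ros_bounds = c(1.0001, 1.5), seed = 0,
                       control = swarm_control(n_starts = 5),
                       rtol = 1e-8, atol = 1e-10) {
  obs <- validate_observations(observations)
  bounds <- bounds %||% default_fit_bounds(free)
  stopifnot(setequal(names(bounds), free),
            all(map_dbl(bounds, 1) < map_dbl(bounds, 2)),
            length(ros_bounds) == 2L, ros_bounds[1] < ros_bounds[2])
  lower_p <- map_dbl(bounds, 1)[free]
  upper_p <- map_dbl(bounds, 2)[free]
  if (control$log_scale) {
    lower <- c(log(lower_p), ros = ros_bounds[1])
    upper <- c(log(upper_p), ros = ros_bounds[2])
  } else {
    lower <- c(lower_p, ros = ros_bounds[1])
    upper <- c(upper_p, ros = ros_bounds[2])
  }
  rmse_fn <- make_rmse_fn(obs, rtol, atol)
  d <- length(free)
  objective <- function(z) {
    th <- if (control$log_scale) exp(z[seq_len(d)]) else z[seq_len(d)]
    p <- tryCatch(do.call(update_params, c(list(params), setNames(as.list(th), free))),
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)
    rmse_fn(p, z[d + 1L])
  }
  res <- swarm_search(objective, lower, upper, seed, control)
  th <- if (control$log_scale) exp(res$par[seq_len(d)]) else res$par[seq_len(d)]
  best_params <- do.call(update_params,
                         c(list(params), setNames(as.list(th), free)))
  best_ros <- unname(res$par[d + 1L])
  report <- list(
    seed = as.integer(seed), free = free,
    bounds = c(bounds, list(initial_ros = ros_bounds)),
    n_particles = control$n_particles, iters = control$iters,
    n_starts = control$n_starts, log_scale = control$log_scale,
    polish = control$polish, starts = res$starts,
    converged = is.finite(res$value),
    n_obs = nrow(obs)
  )
  new_cartox_fit(best_params, best_ros, res$value, report)
}

#' Calibrate only the initial ROS burst
#'
#' One-dimensional seeded swarm fit of `R(0)` with every model parameter
#' held at `params`; used to transfer a calibration to a different impact
#' energy, where only the size of the post-impact ROS burst changes.
#'
#' @inheritParams fit_impact
#' @param bounds Search interval for `R(0)`.
#' @return A `cartox_fit` object (the parameter set equals `params`).
#' @examples
#' \donttest{
#' fit <- fit_initial_ros(impact_observations("14J"), seed = 0)
#' fit$initial_ros
#' }
#' @export
fit_initial_ros <- function(observations, params = cartox_params(),
                            bounds = c(1.0001, 1.5), seed = 0,
                            control = swarm_control(n_particles = 40,
                                                    iters = 80),
                            rtol = 1e-8, atol = 1e-10) {
  obs <- validate_observations(observations)
  stopifnot(inherits(params, "cartox_params"),
            length(bounds) == 2L, bounds[1] < bounds[2])
  rmse_fn <- make_rmse_fn(obs, rtol, atol)
  objective <- function(z) rmse_fn(params, z[1])
  res <- swarm_search(objective, bounds[1], bounds[2], seed, control)
  report <- list(
    seed = as.integer(seed), free = "initial_ros",
    bounds = list(initial_ros = bounds),
    n_particles = control$n_particles, iters = control$iters,
    n_starts = control$n_starts, polish = control$polish,
    starts = res$starts, converged = is.finite(res$value), n_obs = nrow(obs)
  )
  new_cartox_fit(params, unname(res$par[1]), res$value, report)
}

#' @export
print.cartox_fit <- function(x, ...) {
  r <- x$optimizer_report
  cat("<cartox_fit>\n")
  cat(sprintf("  free:          %s\n", paste(r$free, collapse = ", ")))
  cat(sprintf("  R(0):          %.6g\n", x$initial_ros))
  cat(sprintf("  RMSE:          %.6g  (n = %d records)\n",
              x$objective_value, r$n_obs))
  cat(sprintf("  swarm:         %d x %d, %d start(s), seed %d%s\n",
              r$n_particles, r$iters, r$n_starts, r$seed,
              if (isTRUE(r$polish)) ", polished" else ""))
  invisible(x)
}

#' @export
tidy.cartox_fit <- function(x, ...) {
  pt <- tidy(x$parameters)
  pt$role <- ifelse(pt$term %in% x$optimizer_report$free, "fitted", pt$role)
  dplyr::bind_rows(
    tibble(term = "initial_ros", value = x$initial_ros,
           role = if ("initial_ros" %in% c(x$optimizer_report$free, "initial_ros"))
             "fitted" else "fixed"),
    pt
  )
}

#' @export
glance.cartox_fit <- function(x, ...) {
  r <- x$optimizer_report
  tibble(objective_value = x$objective_value, n_obs = r$n_obs,
         initial_ros = x$initial_ros, converged = r$converged,
         seed = r$seed, n_starts = r$n_starts,
         n_particles = r$n_particles, iters = r$iters)
}

#' Serialize a fit to JSON
#'
#' Writes the completed parameter set, fitted `R(0)`, objective value and the
#' optimizer report (seed, bounds, restart summary) as a JSON object.
#'
#' @param fit A `cartox_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cartox_fit"))
  r <- fit$optimizer_report
  obj <- list(
    parameters = as.list(param_vector(fit$parameters)),
    initial_ros = fit$initial_ros,
    objective_value = fit$objective_value,
    optimizer_report = list(
      seed = r$seed, free = r$free, bounds = r$bounds,
      n_particles = r$n_particles, iters = r$iters, n_starts = r$n_starts,
      converged = r$converged, n_obs = r$n_obs,
      starts = r$starts
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
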