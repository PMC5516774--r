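#' Numerically locate an equilibrium of the model
#'
#' Integrates from the guess to a long horizon so that the fast variables
#' settle, then polishes the endpoint by damped Newton iteration on the
#' right-hand side, using the analytic Jacobian through its Moore-Penrose
#' pseudo-inverse. The pseudo-inverse matters: after an impact the system
#' relaxes onto a continuum of rest states (any cell composition with
#' sub-threshold ROS is stationary for `M` and `D`), so the Jacobian at an
#' equilibrium is singular and plain Newton steps are ill-defined.
#'
#' @param params A [cartox_params()] object.
#' @param guess Nonnegative length-5 starting state.
#' @param tolerance Max-norm residual required of the returned state.
#' @param settle_horizon Pre-integration horizon in hours.
#' @param rtol,atol Integration tolerances for the settling run.
#' @return A named length-5 state with attributes `residual` (max-norm of
#'   the right-hand side) and `iterations`. Errors if the residual cannot be
#'   brought below `tolerance`, reporting the best residual reached.
#' @examples
#' find_equilibrium(cartox_params(), c(1, 0, 1, 1, 1))
#' @export
find_equilibrium <- function(params = cartox_params(),
                             guess = c(1, 0, 1, 1, 1), tolerance = 1e-9,
                             settle_horizon = 2e4, rtol = 1e-10,
                             atol = 1e-12) {
  stopifnot(inherits(params, "cartox_params"))
  y <- as_state(guess)
  if (any(y < 0)) abort("`guess` must be nonnegative")
  rhs_vec <- function(state) cartox_rhs(0, state, params)[[1]]
  if (settle_horizon > 0) {
    traj <- simulate_cartox(params, y, times = c(0, settle_horizon / 2,
                                                 settle_horizon),
                            rtol = rtol, atol = atol)
    y <- as_state(traj[nrow(traj), state_names])
  }
  best <- y
  best_res <- max(abs(rhs_vec(y)))
  it <- 0L
  while (best_res > tolerance && it < 50L) {
    it <- it + 1L
    J <- model_jacobian(y, params)
    step <- tryCatch(-drop(MASS::ginv(J) %*% rhs_vec(y)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    while (lambda >= 1 / 64) {
      cand <- pmax(y + lambda * step, 0)
      res <- max(abs(rhs_vec(cand)))
      if (res < best_res) {
        y <- cand
        best <- cand
        best_res <- res
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (best_res > tolerance) {
    abort(sprintf(
      "no equilibrium found: best residual %.3g exceeds tolerance %.3g",
      best_res, tolerance))
  }
  structure(setNames(as.numeric(best), state_names),
            residual = best_res, iterations = it)
}

#' Linear stability of an equilibrium
#'
#' Eigenvalues of the analytic Jacobian at a state whose right-hand side
#' residual is below `residual_tol`. The equilibrium is classified
#' `"stable"` when every real part is non-positive (within `margin`);
#' eigenvalues with `|Re| <= margin` are counted as marginal — expected
#' here, since the post-impact rest states form a continuum (perturbing the
#' cell composition inside the stress-free region gives a neighbouring
#' equilibrium, not a restoring flow).
#'
#' @param params A [cartox_params()] object.
#' @param state An equilibrium state (e.g. from [find_equilibrium()]).
#' @param residual_tol Max-norm residual above which the state is rejected.
#' @param margin Tolerance on zero real parts.
#' @return A list of class `cartox_stability`: `eigenvalues` (complex,
#'   sorted by decreasing real part), `classification` (`"stable"` or
#'   `"unstable"`), `n_marginal`, `residual`.
#' @examples
#' eq <- find_equilibrium(cartox_params(), c(1, 0, 1, 1, 1))
#' stability_eigenvalues(cartox_params(), eq)
#' @export
stability_eigenvalues <- function(params, state, residual_tol = 1e-6,
                                  margin = 1e-8) {
  stopifnot(inherits(params, "cartox_params"))
  y <- as_state(state)
  residual <- max(abs(cartox_rhs(0, y, params)[[1]]))
  if (residual > residual_tol) {
    abort(sprintf(
      "state is not an equilibrium: residual %.3g > %.3g",
      residual, residual_tol))
  }
  ev <- eigen(model_jacobian(y, params), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(
    eigenvalues = ev,
    classification = if (all(Re(ev) <= margin)) "stable" else "unstable",
    n_marginal = sum(abs(Re(ev)) <= margin),
    residual = residual
  ), class = "cartox_stability")
}

#' @export
print.cartox_stability <- function(x, ...) {
  cat("<cartox_stability>", x$classification,
      sprintf("(%d marginal eigenvalue(s), residual %.3g)\n",
              x$n_marginal, x$residual))
  print(x$eigenvalues)
  invisible(x)
}

#' Combined equilibrium report
#'
#' Finds the equilibrium reached from `guess` and classifies its stability;
#' convenient for serialization (the CLI prints it as JSON).
#'
#' @inheritParams find_equilibrium
#' @return A list with `state`, `residual`, `eigenvalues_re`,
#'   `eigenvalues_im`, `classification`, `n_marginal`.
#' @export
equilibrium_report <- function(params = cartox_params(),
                               guess = c(1, 0, 1, 1, 1), tolerance = 1e-9,
                               settle_horizon = 2e4) {
  eq <- find_equilibrium(params, guess, tolerance, settle_horizon)
  st <- stability_eigenvalues(params, eq)
  list(state = as.list(eq),
       residual = attr(eq, "residual"),
       eigenvalues_re = Re(st$eigenvalues),
       eigenvalues_im = Im(st$eigenvalues),
       classification = st$classification,
       n_marginal = st$n_marginal)
}
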