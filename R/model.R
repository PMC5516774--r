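#' Oxidative-stress switch
#'
#' The stress rate experienced by chondrocytes as a function of the relative
#' ROS level. It is zero at or below the control level `R = 1` and grows as
#' `s_C * (R - 1)^alpha` above it; with `alpha > 1` the switch and its first
#' derivative both vanish at the threshold, so the right-hand side of the
#' model stays continuously differentiable.
#'
#' @param ros Relative ROS concentration(s), >= 0. Vectorized.
#' @param s_C Stress scaling constant.
#' @param alpha Stress exponent (> 1).
#' @return Stress rate(s), same length as `ros`.
#' @examples
#' oxidative_stress(c(0.5, 1, 1.5))
#' @export
oxidative_stress <- function(ros, s_C = 9.517, alpha = 1 + 1e-4) {
  if (any(!is.finite(ros))) abort("`ros` must be finite")
  if (any(ros < 0)) abort("`ros` must be >= 0")
  ifelse(ros > 1, s_C * (ros - 1)^alpha, 0)
}

# unvalidated scalar versions for solver internals (the solver may probe
# states a rounding error below zero; R <= 1 already maps to zero stress)
stress_value <- function(R, s_C, alpha) {
  if (R > 1) s_C * (R - 1)^alpha else 0
}

# d(stress)/d(ros); the one-sided limits at ros = 1 agree at 0 for alpha > 1,
# so the kink value is defined as 0
oxidative_stress_deriv <- function(ros, s_C = 9.517, alpha = 1 + 1e-4) {
  ifelse(ros > 1, s_C * alpha * (ros - 1)^(alpha - 1), 0)
}

#' ATP production as a function of ROS per cell
#'
#' Unimodal production law: glycolytic ATP output is maximal when the
#' ROS-per-cell ratio `x` sits at the optimum `R_0`, falls off on either
#' side, and shuts down entirely for `x <= 0` or `x >= 2 R_0` (no oxidant or
#' oxidant excess). Continuous on the whole real line.
#'
#' @param x ROS-per-cell ratio(s). Vectorized.
#' @param k_E Production scale (per hour).
#' @param lambda_E Shape constant.
#' @param R_0 Optimal ROS-per-cell ratio.
#' @return Production rate(s) (per hour).
#' @examples
#' atp_production(c(0, 1 / 1.0001, 2 / 1.0001))
#' @export
atp_production <- function(x, k_E = 0.0961, lambda_E = 0.0418,
                           R_0 = 1 / (1 + 1e-4)) {
  if (any(!is.finite(x))) abort("`x` must be finite")
  ifelse(x <= 0 | x >= 2 * R_0, 0,
         k_E / ((x - R_0)^2 + lambda_E) - k_E / (R_0^2 + lambda_E))
}

# d(atp_production)/dx
atp_production_deriv <- function(x, k_E, lambda_E, R_0) {
  ifelse(x <= 0 | x >= 2 * R_0, 0,
         -2 * k_E * (x - R_0) / ((x - R_0)^2 + lambda_E)^2)
}

state_names <- c("M", "D", "R", "E", "U")

as_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, state_names])
  state <- as.numeric(state)
  if (length(state) != 5L) abort("a state has exactly 5 components (M, D, R, E, U)")
  if (any(!is.finite(state))) abort("state components must be finite")
  setNames(state, state_names)
}

#' Right-hand side of the oxidative-stress ODE system
#'
#' Time derivatives of the five model variables: `M` and `D` (live-cell
#' fractions with functional / dysfunctional mitochondria), `R` (relative
#' ROS), `E` (relative ATP), `U` (relative GAG). Stress converts `M` into `D`
#' and drives apoptosis of `D`; cells release ROS (dysfunctional ones `k_D`
#' times as much) which is cleared at rate `delta_R`; ATP is produced from
#' the ROS-per-cell ratio `R / (M + D + epsilon)` and consumed at rate
#' `delta_E`; GAG follows a logistic law whose carrying level rises with ATP.
#'
#' The signature matches what [deSolve::ode()] expects of an R-level model
#' function; [simulate_cartox()] uses a compiled equivalent by default and
#' this function serves as the transparent reference.
#'
#' @param t Time (hours). Unused (the system is autonomous) but part of the
#'   solver interface.
#' @param state Numeric length-5 state `(M, D, R, E, U)`, all >= 0.
#' @param params A [cartox_params()] object.
#' @return A list whose first element is the length-5 derivative vector.
#' @examples
#' cartox_rhs(0, c(1, 0, 1, 1, 1), cartox_params())
#' @export
cartox_rhs <- function(t, state, params) {
  y <- as_state(state)
  S <- stress_value(y[["R"]], params$s_C, params$alpha)
  x <- y[["R"]] / (y[["M"]] + y[["D"]] + params$epsilon)
  fE <- atp_production(x, params$k_E, params$lambda_E, params$R_0)
  g <- (1 + params$lambda_U) / (1 + params$lambda_U * y[["E"]])
  list(c(
    M = -params$k_S * y[["M"]] * S,
    D = params$k_S * y[["M"]] * S - params$delta_D * y[["D"]] * S,
    R = params$alpha_M * (y[["M"]] + params$k_D * y[["D"]]) -
      params$delta_R * y[["R"]],
    E = fE - params$delta_E * y[["E"]],
    U = params$k_U * y[["U"]] * (1 - g * y[["U"]])
  ))
}

#' Jacobian of the model right-hand side with respect to the state
#'
#' Analytic 5x5 matrix of partial derivatives, used by the forward
#' sensitivity system and by the linear stability analysis. The derivative
#' of the stress switch at its threshold `R = 1` is taken as 0, the common
#' one-sided limit for `alpha > 1`.
#'
#' @param state Numeric length-5 state `(M, D, R, E, U)`.
#' @param params A [cartox_params()] object.
#' @return A 5x5 numeric matrix with rows and columns named `M, D, R, E, U`.
#' @examples
#' model_jacobian(c(1, 0, 1, 1, 1), cartox_params())
#' @export
model_jacobian <- function(state, params) {
  y <- as_state(state)
  M <- y[["M"]]; D <- y[["D"]]; R <- y[["R"]]; E <- y[["E"]]; U <- y[["U"]]
  S <- stress_value(R, params$s_C, params$alpha)
  dS <- oxidative_stress_deriv(R, params$s_C, params$alpha)
  P <- M + D + params$epsilon
  x <- R / P
  fEp <- atp_production_deriv(x, params$k_E, params$lambda_E, params$R_0)
  g <- (1 + params$lambda_U) / (1 + params$lambda_U * E)
  J <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  J["M", ] <- c(-params$k_S * S, 0, -params$k_S * M * dS, 0, 0)
  J["D", ] <- c(params$k_S * S, -params$delta_D * S,
                (params$k_S * M - params$delta_D * D) * dS, 0, 0)
  J["R", ] <- c(params$alpha_M, params$alpha_M * params$k_D,
                -params$delta_R, 0, 0)
  J["E", ] <- c(fEp * (-R / P^2), fEp * (-R / P^2), fEp / P,
                -params$delta_E, 0)
  J["U", ] <- c(0, 0, 0,
                params$k_U * U^2 * (1 + params$lambda_U) * params$lambda_U /
                  (1 + params$lambda_U * E)^2,
                params$k_U * (1 - 2 * g * U))
  J
}

# Partial derivative of the right-hand side with respect to one free
# parameter, holding the state fixed. Perturbing a free parameter re-applies
# the constraint completion: alpha_M follows delta_R, and delta_E follows
# k_E and lambda_E, so the homeostasis constraints hold along the perturbed
# family. These are the forcing vectors F of the forward sensitivity system.
param_partials <- function(state, params, target) {
  y <- as_state(state)
  M <- y[["M"]]; D <- y[["D"]]; R <- y[["R"]]; E <- y[["E"]]; U <- y[["U"]]
  S <- stress_value(R, params$s_C, params$alpha)
  P <- M + D + params$epsilon
  x <- R / P
  fE <- atp_production(x, params$k_E, params$lambda_E, params$R_0)
  interior <- x > 0 && x < 2 * params$R_0
  FF <- setNames(numeric(5), state_names)
  switch(target,
    k_S = {
      FF[["M"]] <- -M * S
      FF[["D"]] <- M * S
    },
    delta_D = {
      FF[["D"]] <- -D * S
    },
    delta_R = { # alpha_M co-varies with delta_R
      FF[["R"]] <- (M + params$k_D * D) - R
    },
    s_C = {
      base <- if (R > 1) (R - 1)^params$alpha else 0
      FF[["M"]] <- -params$k_S * M * base
      FF[["D"]] <- (params$k_S * M - params$delta_D * D) * base
    },
    k_E = { # delta_E co-varies with k_E
      FF[["E"]] <- fE / params$k_E - (params$delta_E / params$k_E) * E
    },
    lambda_E = { # delta_E co-varies with lambda_E
      dfE <- if (interior) {
        -params$k_E / ((x - params$R_0)^2 + params$lambda_E)^2 +
          params$k_E / (params$R_0^2 + params$lambda_E)^2
      } else 0
      ddeltaE <- -params$k_E * (1 + 2 * params$lambda_E) /
        (params$lambda_E * (1 + params$lambda_E))^2
      FF[["E"]] <- dfE - ddeltaE * E
    },
    k_U = {
      g <- (1 + params$lambda_U) / (1 + params$lambda_U * E)
      FF[["U"]] <- U * (1 - g * U)
    },
    lambda_U = {
      FF[["U"]] <- -params$k_U * U^2 * (1 - E) / (1 + params$lambda_U * E)^2
    },
    abort(sprintf("unknown parameter target `%s`", target))
  )
  FF
}
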