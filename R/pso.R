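#' Control settings for the particle-swarm fits
#'
#' @param n_particles Particles per swarm.
#' @param iters Iterations per swarm.
#' @param n_starts Independent swarm restarts (seeds derived from the fit
#'   seed); the best polished restart wins. Restarts are the main defence
#'   against the premature-convergence failure mode of global-best PSO on
#'   ridged objectives.
#' @param inertia,c_personal,c_social Velocity update coefficients
#'   (Clerc-Kennedy constriction defaults).
#' @param polish Run a local polish (Nelder-Mead then box-constrained
#'   L-BFGS-B via [stats::optim()]) from each restart's best point.
#' @param log_scale Search positive rate/shape parameters on the log scale
#'   (the published values span three orders of magnitude). `R(0)` is always
#'   searched on the linear scale.
#' @return A list of class `swarm_control`.
#' @export
swarm_control <- function(n_particles = 60, iters = 200, n_starts = 1,
                          inertia = 0.7298, c_personal = 1.49618,
                          c_social = 1.49618, polish = TRUE,
                          log_scale = TRUE) {
  stopifnot(n_particles >= 2, iters >= 1, n_starts >= 1)
  structure(list(n_particles = n_particles, iters = iters,
                 n_starts = n_starts, inertia = inertia,
                 c_personal = c_personal, c_social = c_social,
                 polish = polish, log_scale = log_scale),
            class = "swarm_control")
}

#' Global-best particle-swarm minimization
#'
#' Minimal seeded PSO over a box: uniform random initialization, constricted
#' velocity update toward personal and global bests, velocity clamping at
#' half the box range, and reflecting boundary handling. Deterministic for a
#' given seed.
#'
#' @param fn Objective function taking a numeric vector, returning a scalar
#'   (non-finite values are treated as `+Inf`).
#' @param lower,upper Finite bounds, `lower < upper` elementwise.
#' @param seed Integer RNG seed.
#' @param control A [swarm_control()] (only the single-swarm fields are
#'   used; restarts and polish are orchestrated by the fitting functions).
#' @return List with `par`, `value`, `n_evals`, `history` (best value per
#'   iteration).
#' @export
ps_optimize <- function(fn, lower, upper, seed = 0,
                        control = swarm_control()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  set.seed(as.integer(seed))
  np <- control$n_particles
  rng <- upper - lower
  evalf <- function(x) {
    v <- suppressWarnings(fn(x))
    if (!is.finite(v)) Inf else v
  }
  X <- sweep(sweep(matrix(runif(np * d), np, d), 2, rng, "*"), 2, lower, "+")
  V <- sweep(matrix(runif(np * d) - 0.5, np, d), 2, rng, "*") * 0.2
  fx <- apply(X, 1, evalf)
  Pb <- X
  fpb <- fx
  g <- which.min(fpb)
  gb <- Pb[g, ]
  fgb <- fpb[g]
  vmax <- 0.5 * rng
  history <- numeric(control$iters)
  for (it in seq_len(control$iters)) {
    r1 <- matrix(runif(np * d), np, d)
    r2 <- matrix(runif(np * d), np, d)
    V <- control$inertia * V +
      control$c_personal * r1 * (Pb - X) +
      control$c_social * r2 * sweep(-X, 2, gb, "+")
    V <- pmin(pmax(V, matrix(-vmax, np, d, byrow = TRUE)),
              matrix(vmax, np, d, byrow = TRUE))
    X <- X + V
    for (j in seq_len(d)) {
      lo <- X[, j] < lower[j]
      X[lo, j] <- 2 * lower[j] - X[lo, j]
      V[lo, j] <- -V[lo, j]
      hi <- X[, j] > upper[j]
      X[hi, j] <- 2 * upper[j] - X[hi, j]
      V[hi, j] <- -V[hi, j]
      X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
    }
    fx <- apply(X, 1, evalf)
    imp <- fx < fpb
    Pb[imp, ] <- X[imp, , drop = FALSE]
    fpb[imp] <- fx[imp]
    g <- which.min(fpb)
    if (fpb[g] < fgb) {
      gb <- Pb[g, ]
      fgb <- fpb[g]
    }
    history[it] <- fgb
  }
  list(par = gb, value = fgb, n_evals = np * (control$iters + 1),
       history = history)
}

# restart + polish orchestration shared by the fitting functions.
# Seeds of the restarts are seed, seed + 1, ... (kept below 2^31).
swarm_search <- function(fn, lower, upper, seed, control) {
  starts <- map(seq_len(control$n_starts) - 1L, function(k) {
    sub_seed <- (as.integer(seed) + k) %% .Machine$integer.max
    res <- ps_optimize(fn, lower, upper, seed = sub_seed, control = control)
    polished <- res
    if (control$polish) {
      nm <- tryCatch(
        if (length(res$par) == 1L) {
          optim(res$par, fn, method = "Brent", lower = lower, upper = upper)
        } else {
          optim(res$par, fn, method = "Nelder-Mead",
                control = list(maxit = 4000, reltol = 1e-13))
        },
        error = function(e) NULL)
      cands <- list(res)
      if (!is.null(nm)) {
        nm_par <- pmin(pmax(nm$par, lower), upper)
        nm_val <- if (all(nm_par == nm$par)) nm$value else fn(nm_par)
        cands <- c(cands, list(list(par = nm_par, value = nm_val)))
        lb <- tryCatch(
          optim(cands[[length(cands)]]$par, fn, method = "L-BFGS-B",
                lower = lower, upper = upper, control = list(maxit = 300)),
          error = function(e) NULL)
        if (!is.null(lb)) cands <- c(cands, list(list(par = lb$par,
                                                      value = lb$value)))
      }
      vals <- map_dbl(cands, "value")
      polished <- cands[[which.min(vals)]]
    }
    list(par = polished$par, value = polished$value, seed = sub_seed,
         swarm_value = res$value, n_evals = res$n_evals)
  })
  best <- starts[[which.min(map_dbl(starts, "value"))]]
  list(par = best$par, value = best$value,
       starts = tibble(
         seed = map_dbl(starts, "seed"),
         swarm_value = map_dbl(starts, "swarm_value"),
         polished_value = map_dbl(starts, "value")))
}
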