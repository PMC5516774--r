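# Shared fixtures and oracles for the test suite.

published_params <- function() cartox_params()

# 14 J/cm2 objective under the pooled reading: the higher-energy experiment
# collected no ATP/GAG data, so the shared lower-energy ATP/GAG records are
# pooled with the 14 J viability series.
pooled_14J_observations <- function() {
  dplyr::bind_rows(
    impact_observations("14J"),
    dplyr::filter(impact_observations("7J"), stream != "viability")
  )
}

# random nonnegative model states for property-style loops; ROS values avoid
# a +/- 1e-3 band around the stress threshold so finite differences of the
# switch are well-conditioned
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r <- if (i %% 2 == 0) runif(1, 0, 0.9) else runif(1, 1.1, 2)
    c(M = runif(1, 0, 1), D = runif(1, 0, 0.5), R = r,
      E = runif(1, 0, 1.5), U = runif(1, 0, 1.5))
  })
}

# central finite-difference sensitivity oracle: d(state)/d(target) on a time
# grid, re-applying the constraint completion for parameter targets so both
# routes perturb the same one-parameter family
fd_sensitivity <- function(params, initial, target, times, h_rel = 1e-4,
                           rtol = 1e-11, atol = 1e-13) {
  ics <- c("M(0)", "D(0)", "R(0)", "E(0)", "U(0)")
  simm <- function(pp, ii) {
    as.matrix(simulate_cartox(pp, ii, times, rtol = rtol,
                              atol = atol)[, c("M", "D", "R", "E", "U")])
  }
  if (target %in% ics) {
    i <- match(target, ics)
    h <- max(abs(initial[i]), 0.01) * h_rel
    ip <- initial; ip[i] <- ip[i] + h
    im <- initial; im[i] <- im[i] - h
    (simm(params, ip) - simm(params, im)) / (2 * h)
  } else {
    v <- params[[target]]
    h <- v * h_rel
    pp <- do.call(update_params, setNames(list(params, v + h), c("params", target)))
    pm <- do.call(update_params, setNames(list(params, v - h), c("params", target)))
    (simm(pp, initial) - simm(pm, initial)) / (2 * h)
  }
}

# forward-sensitivity raw values as a times x 5 matrix (M, D, R, E, U columns)
forward_sensitivity_matrix <- function(params, initial, target, times,
                                       rtol = 1e-11, atol = 1e-13) {
  s <- sensitivity_trajectories(params, initial, target, times,
                                rtol = rtol, atol = atol)
  matrix(s$raw, ncol = 5, byrow = TRUE,
         dimnames = list(NULL, c("M", "D", "R", "E", "U")))
}
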