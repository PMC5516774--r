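p_pub <- published_params()

test_that("stress switch is off at and below threshold and scales as expected", {
  expect_identical(oxidative_stress(1), 0)
  expect_identical(oxidative_stress(0.5), 0)
  # (2 - 1)^alpha = 1 for any alpha, so the value is exactly s_C
  expect_equal(oxidative_stress(2, s_C = 9.517, alpha = 1 + 1e-4), 9.517)
  expect_error(oxidative_stress(-0.1), ">= 0")
})

test_that("stress switch and its derivative vanish at the threshold", {
  expect_identical(oxidative_stress(1), 0)
  expect_identical(oxidative_stress(1 - 1e-9), 0)
  hs <- 10^(-(3:7))
  # continuity at the threshold: S(1 + h) -> 0 at the rate h^alpha
  expect_true(all(abs(oxidative_stress(1 + hs)) <= 9.6 * hs^1.0001))
  # one-sided difference quotients of S vanish as h -> 0 when the exponent
  # is visibly above 1; at the default alpha = 1 + 1e-4 the same limit holds
  # but only inside an exponentially thin layer (h^(alpha-1) ~ 1 for any
  # representable h), so the decay is asserted at exponents where floating
  # point can resolve it
  for (a in c(1.5, 2)) {
    dq <- oxidative_stress(1 + hs, alpha = a) / hs
    expect_true(all(diff(dq) < 0))
    expect_lt(dq[length(dq)], 9.6 * hs[length(hs)]^(a - 1))
  }
  # the implementation's kink derivative is the one-sided C1 limit, 0
  expect_identical(cartox:::oxidative_stress_deriv(1), 0)
})

test_that("ATP production is continuous with a unique interior maximum", {
  p <- p_pub
  expect_identical(atp_production(0), 0)
  expect_identical(atp_production(2 * p$R_0), 0)
  # hand-evaluated oracle at the optimum
  peak <- p$k_E / p$lambda_E - p$k_E / (p$R_0^2 + p$lambda_E)
  expect_equal(atp_production(p$R_0), peak, tolerance = 1e-12)
  expect_equal(peak, 2.2068, tolerance = 1e-4)

  # dense grid scan: continuity at both shut-off points, max uniquely at R_0
  x <- seq(-0.5, 2 * p$R_0 + 0.5, length.out = 20001)
  fx <- atp_production(x)
  expect_lt(abs(atp_production(1e-9)), 1e-5)
  expect_lt(abs(atp_production(2 * p$R_0 - 1e-9)), 1e-5)
  expect_lt(max(abs(diff(fx))), 0.01)           # no jumps on the fine grid
  expect_equal(x[which.max(fx)], p$R_0, tolerance = 1e-3)
  expect_true(all(fx <= peak + 1e-12))
})

test_that("right-hand side matches hand-computed values", {
  # homeostasis: residual is zero except the O(epsilon) ATP term
  d0 <- cartox_rhs(0, c(1, 0, 1, 1, 1), p_pub)[[1]]
  expect_lt(max(abs(d0)), 10 * p_pub$epsilon)

  # with R = 2 the M-equation reads -k_S * s_C * (2-1)^alpha exactly
  d <- cartox_rhs(0, c(1, 0, 2, 1, 1), p_pub)[[1]]
  expect_equal(d[["M"]], -2.7938 * 9.517, tolerance = 1e-12)

  # below the stress threshold with D = 0 the cell equations are frozen
  d <- cartox_rhs(0, c(0.8, 0, 0.9, 1, 1), p_pub)[[1]]
  expect_identical(d[["M"]], 0)
  expect_identical(d[["D"]], 0)

  expect_error(cartox_rhs(0, c(1, 0, NaN, 1, 1), p_pub), "finite")
})

test_that("cell-loss ordering holds on random nonnegative states", {
  for (y in random_states(40)) {
    d <- cartox_rhs(0, y, p_pub)[[1]]
    S <- oxidative_stress(y[["R"]], p_pub$s_C, p_pub$alpha)
    expect_lte(d[["M"]], 0)
    expect_equal(d[["M"]] + d[["D"]], -p_pub$delta_D * y[["D"]] * S,
                 tolerance = 1e-12)
    expect_lte(d[["M"]] + d[["D"]], 0)
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  h <- 1e-6
  for (y in random_states(12, seed = 7)) {
    J <- model_jacobian(y, p_pub)
    Jfd <- matrix(0, 5, 5)
    for (j in 1:5) {
      yp <- y; yp[j] <- yp[j] + h
      ym <- y; ym[j] <- ym[j] - h
      Jfd[, j] <- (cartox_rhs(0, yp, p_pub)[[1]] -
                     cartox_rhs(0, ym, p_pub)[[1]]) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd), 1), 1e-5)
  }
})
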