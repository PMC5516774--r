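p_pub <- published_params()
impact_init <- c(1, 0, 1.0202, 1, 1)

test_that("sensitivities start at zero for parameters and indicators for initial conditions", {
  tt <- seq(0, 4, 1)
  s <- sensitivity_trajectories(p_pub, impact_init, "k_S", tt)
  expect_identical(dplyr::filter(s, time_h == 0)$raw, rep(0, 5))
  s <- sensitivity_trajectories(p_pub, impact_init, "R(0)", tt)
  expect_identical(dplyr::filter(s, time_h == 0)$raw, c(0, 0, 1, 0, 0))
  # relative sensitivity is undefined where the variable is ~ 0
  s <- sensitivity_trajectories(p_pub, impact_init, "D(0)", tt)
  d0 <- dplyr::filter(s, time_h == 0, variable == "D")
  expect_identical(d0$raw, 1)
  expect_true(is.na(d0$relative))
})

test_that("variables without feedback paths have identically zero sensitivities", {
  tt <- seq(0, 72, 4)
  s_u <- sensitivity_trajectories(p_pub, impact_init, "U(0)", tt)
  expect_lt(max(abs(dplyr::filter(s_u, variable %in% c("M", "D", "R", "E"))$raw)),
            1e-30)
  s_e <- sensitivity_trajectories(p_pub, impact_init, "E(0)", tt)
  expect_lt(max(abs(dplyr::filter(s_e, variable %in% c("M", "D", "R"))$raw)),
            1e-30)
})

test_that("forward sensitivities match finite differences for representative targets", {
  # interior reference state so central differences are valid for every
  # initial-condition target
  init <- c(1, 0.01, 1.0202, 1, 1)
  tt <- seq(0, 72, 4)
  for (tg in c("k_S", "lambda_E", "R(0)", "D(0)")) {
    fwd <- forward_sensitivity_matrix(p_pub, init, tg, tt)
    fd <- fd_sensitivity(p_pub, init, tg, tt)
    scale <- max(abs(fd), 1e-3)
    expect_lt(max(abs(fwd - fd)) / scale, 1e-3)
  }
})

test_that("stress-free trajectories keep the relative M sensitivity at one", {
  # while the stress switch never fires, M(t) = M(0) exactly and the
  # forward system gives d M(t) / d M(0) = 1 identically
  for (init in list(c(1, 0, 1, 1, 1), c(1, 0, 0.98, 1, 1))) {
    s <- sensitivity_trajectories(p_pub, init, "M(0)", seq(0, 336, 8))
    relM <- dplyr::filter(s, variable == "M")$relative
    expect_equal(relM, rep(1, length(relM)), tolerance = 1e-8)
  }
})

test_that("parameter perturbations leave the control trajectory unmoved", {
  # the homeostasis constraints are re-applied along each perturbed family,
  # so no parameter moves the control state: all M sensitivities vanish
  for (tg in c("k_S", "delta_D", "delta_R", "s_C")) {
    s <- sensitivity_trajectories(p_pub, c(1, 0, 1, 1, 1), tg, seq(0, 72, 4))
    expect_lt(max(abs(dplyr::filter(s, variable == "M")$raw)), 1e-8)
  }
})

test_that("the report ranks the ROS burst first among initial conditions", {
  rep <- sensitivity_report(p_pub, impact_init, times = seq(0, 72, 2))
  summ <- sensitivity_summary(rep)
  ics <- dplyr::filter(summ, type == "initial_condition")
  expect_identical(ics$target[which.max(ics$max_abs_relative)], "R(0)")
  expect_identical(nrow(summ), 13L)
  # the ATP starting level has no lasting influence on matrix content
  s_e <- dplyr::filter(rep$trajectories, target == "E(0)", variable == "U")
  expect_lt(abs(s_e$relative[which.max(s_e$time_h)]), 1e-6)
})

test_that("unknown targets are rejected", {
  expect_error(sensitivity_trajectories(p_pub, impact_init, "epsilon"),
               "epsilon")
  expect_error(sensitivity_trajectories(p_pub, impact_init, "Z(0)"), "Z")
})
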