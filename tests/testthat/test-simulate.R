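p_pub <- published_params()

test_that("homeostasis state is preserved over the full horizon", {
  traj <- simulate_cartox(p_pub, c(1, 0, 1, 1, 1), times = seq(0, 336, 4))
  for (v in c("M", "D", "R", "E", "U")) {
    expect_lt(max(abs(traj[[v]] - traj[[v]][1])), 1e-4)
  }
  expect_equal(unlist(traj[1, c("M", "D", "R", "E", "U")]),
               c(M = 1, D = 0, R = 1, E = 1, U = 1))
})

test_that("compiled and R right-hand sides integrate identically", {
  tc <- simulate_impact(p_pub, 1.0202, seq(0, 72, 1), engine = "compiled")
  tr <- simulate_impact(p_pub, 1.0202, seq(0, 72, 1), engine = "r")
  expect_lt(max(abs(as.matrix(tc[, 2:6]) - as.matrix(tr[, 2:6]))), 1e-12)
})

test_that("tightening tolerances leaves the trajectory unchanged at 1e-6", {
  tt <- seq(0, 336, 4)
  a <- simulate_impact(p_pub, 1.0202, tt, rtol = 1e-8, atol = 1e-10)
  b <- simulate_impact(p_pub, 1.0202, tt, rtol = 5e-9, atol = 5e-11)
  c <- simulate_impact(p_pub, 1.0202, tt, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(as.matrix(a[, 2:6]) - as.matrix(b[, 2:6]))), 1e-6)
  expect_lt(max(abs(as.matrix(a[, 2:6]) - as.matrix(c[, 2:6]))), 1e-6)
})

test_that("trajectories stay nonnegative and monotone where the model says so", {
  for (r0 in c(1.0202, 1.036, 1.2)) {
    traj <- simulate_impact(p_pub, r0, seq(0, 336, 2))
    expect_gt(min(as.matrix(traj[, 2:6])), -1e-8)
    expect_true(all(diff(traj$M) <= 1e-10))
    expect_true(all(diff(traj$viability) <= 1e-10))
    expect_true(all(traj$viability <= traj$viability[1] + 1e-10))
  }
})

test_that("sub-threshold initial ROS never triggers stress", {
  traj <- simulate_impact(p_pub, 0.9, seq(0, 336, 4))
  expect_equal(traj$M, rep(1, nrow(traj)), tolerance = 1e-8)
  expect_lt(max(abs(traj$D)), 1e-8)
})

test_that("derived observables match their definitions", {
  traj <- simulate_cartox(p_pub, c(1, 0, 1, 1, 1), times = seq(0, 24, 1))
  expect_equal(viability(traj), traj$M + traj$D)
  expect_equal(ros_per_cell(traj), traj$R / (traj$M + traj$D + p_pub$epsilon))
  expect_equal(ros_per_cell(traj)[1], 1 / (1 + p_pub$epsilon))
  t7 <- simulate_impact(p_pub, 1.0202, seq(0, 1, 0.5))
  expect_equal(ros_per_cell(t7)[1], 1.0202 / (1 + p_pub$epsilon))
  expect_equal(t7$viability[1], 1)
})

test_that("input contracts are enforced", {
  expect_error(simulate_cartox(p_pub, c(1, 0, -0.1, 1, 1)), "nonnegative")
  expect_error(simulate_cartox(p_pub, times = c(1, 2, 3)), "start at 0")
  expect_error(simulate_cartox(p_pub, times = c(0, 2, 2)), "increasing")
  expect_error(simulate_impact(p_pub, initial_ros = -1), "nonnegative")
})

test_that("trajectory CSV export has the documented columns", {
  traj <- simulate_impact(p_pub, 1.0202, seq(0, 12, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(back),
                   c("time_h", "M", "D", "R", "E", "U", "viability",
                     "ros_per_cell"))
  expect_equal(back$viability, traj$viability, tolerance = 1e-12)
})
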