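p_pub <- published_params()

test_that("pooled RMSE matches a hand-computed two-record oracle", {
  # at homeostasis (R(0) = 1) the predicted viability is 1 up to O(epsilon),
  # so residuals are set directly by the observed means:
  # sqrt((0.3^2 + 0.4^2) / 2) = 0.3535534
  obs <- tibble::tibble(stream = "viability", time_h = c(24, 48),
                        mean = c(0.7, 0.6), sd = 0)
  expect_equal(rmse_objective(obs, p_pub, initial_ros = 1),
               sqrt((0.09 + 0.16) / 2), tolerance = 1e-3)
})

test_that("objective is zero on self-generated noise-free data", {
  obs <- predict_observations(impact_observations("7J"), p_pub, 1.0202)
  obs$mean <- obs$.fitted
  expect_lt(rmse_objective(obs, p_pub, 1.0202), 1e-8)
})

test_that("objective is deterministic", {
  a <- rmse_objective(impact_observations("7J"), p_pub, 1.0202)
  b <- rmse_objective(impact_observations("7J"), p_pub, 1.0202)
  expect_identical(a, b)
})

test_that("published calibration reproduces the frozen objective values", {
  # regression values computed with this model at tolerances 1e-8/1e-10;
  # the acceptance suite compares them against the printed study values
  expect_equal(rmse_objective(impact_observations("7J"), p_pub, 1.0202),
               0.07106935, tolerance = 1e-5)
  expect_equal(rmse_objective(impact_observations("14J"), p_pub, 1.036),
               0.14345680, tolerance = 1e-5)
  expect_equal(rmse_objective(pooled_14J_observations(), p_pub, 1.036),
               0.12295788, tolerance = 1e-5)
})

test_that("a degenerate search box returns the published point", {
  free <- c("k_S", "delta_D", "delta_R", "s_C", "k_E", "lambda_E", "lambda_U")
  bounds <- lapply(free, function(nm) p_pub[[nm]] * c(1 - 1e-9, 1 + 1e-9))
  names(bounds) <- free
  fit <- fit_impact(impact_observations("7J"), p_pub, free = free,
                    bounds = bounds,
                    ros_bounds = 1.0202 * c(1 - 1e-9, 1 + 1e-9), seed = 0,
                    control = swarm_control(n_particles = 5, iters = 3,
                                            n_starts = 1, polish = FALSE))
  expect_equal(fit$initial_ros, 1.0202, tolerance = 1e-6)
  expect_equal(fit$parameters$k_S, p_pub$k_S, tolerance = 1e-6)
  expect_equal(fit$objective_value, 0.0711, tolerance = 1e-3)
})

test_that("seeded fits are bit-reproducible", {
  ctrl <- swarm_control(n_particles = 12, iters = 15)
  a <- fit_initial_ros(impact_observations("14J"), p_pub, seed = 3, control = ctrl)
  b <- fit_initial_ros(impact_observations("14J"), p_pub, seed = 3, control = ctrl)
  expect_identical(a$initial_ros, b$initial_ros)
  expect_identical(a$objective_value, b$objective_value)
  # without the local polish the raw swarm output depends on the seed
  ctrl_raw <- swarm_control(n_particles = 12, iters = 6, polish = FALSE)
  c1 <- fit_initial_ros(impact_observations("14J"), p_pub, seed = 3,
                        control = ctrl_raw)
  c2 <- fit_initial_ros(impact_observations("14J"), p_pub, seed = 4,
                        control = ctrl_raw)
  expect_false(identical(c1$initial_ros, c2$initial_ros))
})

test_that("noise-free single-parameter recovery nails the generating R(0)", {
  des <- dplyr::mutate(observation_design("7J"), sd = 0)
  obs <- simulate_observations(p_pub, 1.05, des, seed = 1)
  fit <- fit_initial_ros(dplyr::filter(obs, stream == "viability"), p_pub,
                         seed = 0,
                         control = swarm_control(n_particles = 16, iters = 30))
  expect_lt(abs(fit$initial_ros - 1.05), 1e-3)
  expect_lt(fit$objective_value, 1e-6)
})

test_that("increasing the ROS burst never increases end-horizon viability", {
  ends <- vapply(seq(1.0, 1.2, by = 0.01), function(r0) {
    traj <- simulate_impact(p_pub, r0, times = seq(0, 72, 1))
    traj$viability[nrow(traj)]
  }, numeric(1))
  expect_true(all(diff(ends) <= 1e-10))
})

test_that("the swarm optimizer solves standard box problems deterministically", {
  sphere <- function(x) sum((x - c(0.3, -0.2))^2)
  a <- ps_optimize(sphere, c(-2, -2), c(2, 2), seed = 1,
                   control = swarm_control(n_particles = 25, iters = 60))
  expect_lt(a$value, 1e-4)
  b <- ps_optimize(sphere, c(-2, -2), c(2, 2), seed = 1,
                   control = swarm_control(n_particles = 25, iters = 60))
  expect_identical(a$par, b$par)
  # bound handling: optimum outside the box lands on the boundary
  d <- ps_optimize(function(x) (x - 5)^2, 0, 2, seed = 1,
                   control = swarm_control(n_particles = 10, iters = 40))
  expect_equal(unname(d$par), 2, tolerance = 1e-4)
})

test_that("fit accessors expose a tidy summary", {
  ctrl <- swarm_control(n_particles = 8, iters = 5)
  fit <- fit_initial_ros(impact_observations("14J"), p_pub, seed = 0,
                         control = ctrl)
  g <- glance(fit)
  expect_identical(g$n_obs, 9L)
  expect_identical(g$seed, 0L)
  expect_true(g$objective_value >= 0)
  td <- tidy(fit)
  expect_identical(td$role[td$term == "initial_ros"], "fitted")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$initial_ros, fit$initial_ros, tolerance = 1e-12)
  expect_equal(back$parameters$delta_E, p_pub$delta_E, tolerance = 1e-12)
})
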