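test_that("noiseless fusion recovers velocity and duration", {
  for (D in c(30, 60)) {
    ses <- noiseless_session(D)
    fit <- noiseless_fit(D)
    v_true <- truth_velocity_at(ses$truth, fit$t_s + fit$estimate$t)
    expect_lt(sqrt(mean((fit$estimate$v_est - v_true)^2)), 0.05)
    expect_lt(abs(fit$T_est - ses$truth$T_true) / ses$truth$T_true, 0.005)
    expect_equal(fit$estimate$x[1L], 0)
  }
})

test_that("the pipeline is deterministic for identical inputs", {
  ses <- sprint_session(distance = 40, seed = 2)
  f1 <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  f2 <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$estimate$v_est, f2$estimate$v_est)
})

test_that("estimated duration shrinks strictly with the distance", {
  ses <- noiseless_session(60)
  fit <- noiseless_fit(60)
  T_est <- vapply(c(60, 45, 30), function(D) {
    cfg <- ses$config
    cfg$distance <- D
    win <- segment_sprint(fit$accel, ses$gnss, cfg)
    estimate_velocity(fit$accel, ses$gnss, win, cfg)$T_est
  }, numeric(1L))
  expect_true(all(diff(T_est) < 0))
})

test_that("withholding GNSS leaves strapdown drift that grows with gyro bias", {
  err_for_bias <- function(bias) {
    ns <- noise_model(seed = 6L)
    ns$gyro_bias <- bias
    ses <- sprint_session(distance = 60, noise = ns)
    fit <- sprint_velocity(ses$imu, ses$gnss, ses$config)
    sd_run <- strapdown_velocity(fit$accel, fit$window, ses$config)
    v_true <- truth_velocity_at(ses$truth, fit$t_s + sd_run$t)
    abs(sd_run$v_est[length(sd_run$v_est)] - v_true[length(v_true)])
  }
  expect_gt(err_for_bias(0.02), err_for_bias(0.002))
})

test_that("fused velocity stays in a physically sane envelope", {
  ses <- sprint_session(distance = 60, seed = 0)
  fit <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  expect_true(all(fit$estimate$v_est > -0.5))
  expect_true(all(fit$estimate$v_est < 13))
  # unimodal rise: the maximum sits in the last two thirds of the sprint
  expect_gt(which.max(fit$estimate$v_est) / length(fit$estimate$v_est), 1 / 3)
})

test_that("max_velocity returns the series maximum", {
  est <- structure(list(v_est = c(1, 2, 3)), class = "velocity_estimate")
  expect_equal(max_velocity(est), 3)
  expect_equal(max_velocity(structure(list(v_est = rep(4.2, 5)),
                                      class = "velocity_estimate")), 4.2)
  expect_error(max_velocity(structure(list(v_est = numeric(0)),
                                      class = "velocity_estimate")), "empty")
  fit <- noiseless_fit(60)
  expect_equal(max_velocity(fit$estimate), fit$v_max)
  expect_equal(fit$v_max, 10.107, tolerance = 0.01)
})

test_that("GNSS latency is estimated near the simulated lag", {
  ses <- sprint_session(distance = 60, seed = 0)
  fit <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  expect_gte(fit$gnss_lag, 0.1)
  expect_lte(fit$gnss_lag, 0.7)
  # and is zero for ideal, lag-free streams
  expect_identical(noiseless_fit(30)$gnss_lag, 0)
})

test_that("result files round-trip the estimate", {
  fit <- noiseless_fit(30)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_result_csv(fit, csv)
  back <- read.csv(csv)
  expect_named(back, c("t", "v_est", "p"))
  expect_equal(back$v_est, fit$estimate$v_est, tolerance = 1e-12)
  write_summary_json(fit, js)
  s <- jsonlite::read_json(js)
  expect_equal(s$T_est, fit$T_est, tolerance = 1e-9)
})
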