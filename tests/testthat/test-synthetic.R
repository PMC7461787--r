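test_that("velocity profiles evaluate their closed forms", {
  gt1 <- velocity_profile("order1", vmax = 10, tau = 1.2, distance = 40)
  expect_equal(gt1$v_fun(1.2), 10 * (1 - exp(-1)), tolerance = 1e-12)

  gt2 <- velocity_profile("order2", distance = 60)  # a=10.5, -0.005, -0.8
  expect_equal(gt2$v_fun(0), 0)
  t_apex <- log(0.005 / 0.8) / (-0.8 + 0.005)
  v_apex <- 10.5 * (exp(-0.005 * t_apex) - exp(-0.8 * t_apex))
  expect_equal(gt2$v_fun(t_apex), v_apex, tolerance = 1e-12)
  expect_gt(v_apex, 10.0)
  # duration solves x(T) = D to 1e-9
  expect_lt(abs(gt2$x_fun(gt2$T_true) - 60), 1e-6)
  # analytic derivative matches a central difference
  h <- 1e-6
  expect_equal(gt2$a_fun(2), (gt2$v_fun(2 + h) - gt2$v_fun(2 - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("profile constructors reject invalid parameters", {
  expect_error(velocity_profile("order1", vmax = -1, tau = 1), "order1")
  expect_error(velocity_profile("order2", a = 10, tau1 = -0.8, tau2 = -0.5),
               "order2")
  expect_error(velocity_profile(distance = -10), "distance")
})

test_that("static IMU samples carry gravity only, rotated by the lean", {
  gt <- velocity_profile(distance = 30, pitch = NULL)
  imu <- simulate_imu(gt, noise_free())
  stat <- imu$t < gt$static_duration
  expect_lt(max(abs(imu$acc[stat, 1])), 1e-12)
  expect_lt(max(abs(imu$acc[stat, 2] - standard_gravity())), 1e-12)
  expect_lt(max(abs(imu$gyr[stat, ])), 1e-12)

  # a 90 degree constant lean puts gravity on the sensor's forward axis
  gt90 <- velocity_profile(distance = 30,
                           pitch = list(lean_start = 90, lean_end = 90,
                                        lean_dist = 20, osc_amp = 0,
                                        osc_freq = 4))
  imu90 <- simulate_imu(gt90, noise_free())
  stat <- imu90$t < gt90$static_duration
  expect_lt(max(abs(abs(imu90$acc[stat, 1]) - standard_gravity())), 1e-9)
  expect_lt(max(abs(imu90$acc[stat, 2])), 1e-9)
})

test_that("simulators are deterministic in the seed and share the truth", {
  ns <- noise_model(seed = 7L)
  gt <- velocity_profile(distance = 30)
  expect_identical(simulate_imu(gt, ns), simulate_imu(gt, ns))
  expect_identical(simulate_gnss(gt, ns), simulate_gnss(gt, ns))
  expect_identical(simulate_radar(gt, ns), simulate_radar(gt, ns))

  s1 <- sprint_session(distance = 30, seed = 1)
  s2 <- sprint_session(distance = 30, seed = 2)
  expect_identical(s1$truth$T_true, s2$truth$T_true)
  expect_false(identical(s1$imu$acc, s2$imu$acc))
})

test_that("noiseless GNSS and radar reproduce the truth on their grids", {
  gt <- velocity_profile(distance = 40)
  gnss <- simulate_gnss(gt, noise_free())
  expect_equal(gnss$fs, 10)
  expect_equal(gnss$v, truth_velocity_at(gt, gnss$t), tolerance = 1e-12)

  radar <- simulate_radar(gt, noise_free())
  expect_equal(radar$fs, 50)
  expect_equal(radar$v, gt$v_fun(radar$t), tolerance = 1e-12)
})

test_that("GNSS lag on a rising profile only underestimates", {
  gt <- velocity_profile(distance = 30)
  ns <- noise_free()
  ns$gnss_lag <- 0.4
  lagged <- simulate_gnss(gt, ns)
  exact <- truth_velocity_at(gt, lagged$t)
  expect_true(all(lagged$v <= exact + 1e-12))
})

test_that("integrating the noiseless global acceleration recovers v_true", {
  gt <- velocity_profile(distance = 60)
  t <- seq(0, 10, by = 1 / 200)
  v_int <- integrate_velocity(t, gt$a_fun(t))
  expect_lt(max(abs(v_int - gt$v_fun(t))), 1e-3)
})

test_that("radar noise magnitude matches its nominal sigma", {
  # constant-speed truth stub isolates the noise process
  gt <- structure(list(v_fun = function(t) rep(8, length(t)),
                       static_duration = 0, T_true = 200),
                  class = "sprint_truth")
  ns <- noise_model(radar_sigma = 0.1, seed = 5L)
  rad <- simulate_radar(gt, ns, duration = 200)
  expect_gt(length(rad$v), 9999L)
  expect_lt(abs(sd(rad$v - 8) - 0.1), 0.01)
})

test_that("sessions bundle photocells consistent with the truth", {
  ses <- sprint_session(distance = 30, seed = 0)
  expect_equal(diff(ses$config$photocell_times), ses$truth$T_true)
  s60 <- sprint_session(distance = 60, seed = 0)
  expect_lt(ses$truth$T_true, s60$truth$T_true)
})

test_that("simulate() draws sessions with consecutive seeds", {
  gt <- velocity_profile(distance = 30)
  out <- simulate(gt, nsim = 2, seed = 10L)
  expect_length(out, 2L)
  expect_identical(out[[1]]$noise$seed, 10L)
  expect_identical(out[[2]]$noise$seed, 11L)
  expect_false(identical(out[[1]]$gnss$v, out[[2]]$gnss$v))
})
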