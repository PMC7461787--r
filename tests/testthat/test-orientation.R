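test_that("quaternion algebra satisfies the rotation identities", {
  set.seed(3)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    v <- rnorm(3)
    r <- quat_rotate(q, v)
    # isometry and conjugate inverse
    expect_lt(abs(sqrt(sum(r^2)) - sqrt(sum(v^2))), 1e-9)
    expect_lt(max(abs(quat_rotate(quat_conjugate(q), r) - v)), 1e-9)
  }
  # axis-angle: 90 degrees about Z maps X to Y
  q <- quat_axis_angle(c(0, 0, 1), pi / 2)
  expect_lt(max(abs(quat_rotate(q, c(1, 0, 0)) - c(0, 1, 0))), 1e-12)
  # Hamilton product is associative
  p <- quat_normalize(rnorm(4)); q <- quat_normalize(rnorm(4))
  r <- quat_normalize(rnorm(4))
  expect_equal(quat_multiply(quat_multiply(p, q), r),
               quat_multiply(p, quat_multiply(q, r)), tolerance = 1e-12)
})

test_that("initial orientation maps the static vector to the vertical", {
  g <- standard_gravity()
  expect_equal(initial_orientation(c(0, g, 0)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  q <- initial_orientation(c(g, 0, 0))
  expect_lt(max(abs(quat_rotate(q, c(g, 0, 0)) - c(0, g, 0))), 1e-9)
  expect_error(initial_orientation(c(0, 4, 0)), "static")
})

test_that("pure gyro integration recovers a constant-rate rotation", {
  omega <- 1.3
  t <- seq(0, 2, by = 1 / 200)
  n <- length(t)
  imu <- imu_recording(t, matrix(0, n, 3),
                       cbind(0, 0, rep(omega, n)))
  qs <- run_orientation_filter(imu, c(1, 0, 0, 0), beta = 0)
  q_end <- qs$q[n, ]
  q_exp <- quat_axis_angle(c(0, 0, 1), omega * (t[n] - t[1]))
  ang <- 2 * acos(min(1, abs(sum(q_end * q_exp))))
  expect_lt(ang, 1e-6)
})

test_that("the gradient step is a descent direction on static input", {
  g <- standard_gravity()
  n <- 201L
  t <- (0:(n - 1L)) / 200
  imu <- imu_recording(t, matrix(rep(c(0, g, 0), each = n), n),
                       matrix(0, n, 3))
  q0 <- quat_axis_angle(c(1, 0, 0), 10 * pi / 180)  # 10 deg off gravity
  qs <- run_orientation_filter(imu, q0, beta = 0.1)
  pred_err <- apply(qs$q, 1L, function(q) {
    sqrt(sum((quat_rotate(quat_conjugate(q), c(0, 1, 0)) - c(0, 1, 0))^2))
  })
  expect_true(all(diff(pred_err[1:100]) < 0))
})

test_that("emitted quaternions stay unit norm under noisy input", {
  ses <- sprint_session(distance = 30, seed = 4)
  fit <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  norms <- sqrt(rowSums(fit$quats$q^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
})

test_that("gravity is removed without systematic leak on static data", {
  g <- standard_gravity()
  n <- 401L
  t <- (0:(n - 1L)) / 200
  set.seed(21)
  acc <- matrix(rep(c(0, g, 0), each = n), n) +
    matrix(rnorm(3L * n, sd = 0.02), n)
  imu <- imu_recording(t, acc, matrix(0, n, 3))
  q0 <- initial_orientation(colMeans(acc[1:200, ]))
  qs <- run_orientation_filter(imu, q0, beta = 0.1)
  a_gf <- to_global_acceleration(imu, qs)
  expect_lt(abs(mean(a_gf$a_gfx)), 0.01)
})

test_that("global acceleration matches the analytic truth on a noiseless sprint", {
  ses <- noiseless_session(60)
  fit <- noiseless_fit(60)
  tr <- ses$truth
  sel <- fit$accel$t >= fit$t_s & fit$accel$t <= fit$t_e
  a_true <- ifelse(fit$accel$t[sel] >= tr$static_duration,
                   tr$a_fun(pmax(fit$accel$t[sel] - tr$static_duration, 0)), 0)
  expect_lt(sqrt(mean((fit$accel$a_gfx[sel] - a_true)^2)), 0.05)
})

test_that("identity rotation removes gravity exactly", {
  g <- standard_gravity()
  imu <- imu_recording(c(0, 0.005), matrix(rep(c(0, g, 0), each = 2), 2),
                       matrix(0, 2, 3))
  quats <- structure(list(t = imu$t, q = matrix(rep(c(1, 0, 0, 0), each = 2), 2)),
                     class = "quaternion_series")
  out <- to_global_acceleration(imu, quats)
  expect_equal(max(abs(out$a_gf)), 0)
  expect_error(to_global_acceleration(imu,
                                      structure(list(t = 0, q = matrix(c(1, 0, 0, 0), 1)),
                                                class = "quaternion_series")),
               "lengths differ")
})

test_that("the quiescence search avoids windows contaminated by motion", {
  ses <- sprint_session(distance = 30, seed = 9)  # default lagged GNSS
  t_s <- detect_start(ses$gnss, ses$config$coarse_start, 0.3)
  sw <- find_static_window(ses$imu, ses$config$coarse_start, t_s, 1.0)
  expect_lte(sw[2L], ses$truth$static_duration + 0.05)
  expect_equal(sw[2L] - sw[1L], 1.0)
})
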