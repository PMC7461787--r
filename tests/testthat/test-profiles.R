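test_that("first-order fits recover the generating time constant", {
  # the amplitude is anchored at the observed maximum, so the series must
  # effectively reach its plateau for tau to be identified exactly
  t <- seq(0, 30, by = 0.02)
  v <- 10 * (1 - exp(-t / 1.3))
  m <- fit_first_order(t, v, "max")
  expect_lt(abs(coef(m)[["tau"]] - 1.3), 1e-6)
  expect_lt(m$rms, 1e-6)
  # closed-form model value
  m12 <- fit_first_order(t, 10 * (1 - exp(-t / 1.2)), "max")
  expect_equal(predict(m12, t = 1.2), 10 * (1 - exp(-1)), tolerance = 1e-6)
})

test_that("the end anchor differs from the max anchor on decaying data", {
  t <- seq(0, 8, by = 0.02)
  v <- 10.5 * (exp(-0.02 * t) - exp(-0.8 * t))  # rises then decays
  m_end <- fit_first_order(t, v, "end")
  expect_lt(m_end$coef[["vmax"]], max(v))
  expect_error(fit_first_order(t, -v, "max"), "anchor")
})

test_that("second-order fits recover their generating parameters", {
  t <- seq(0, 7, by = 0.02)
  v <- 10.5 * (exp(-0.005 * t) - exp(-0.8 * t))
  m <- fit_second_order(t, v)
  cf <- coef(m)
  expect_lt(abs(cf[["a"]] - 10.5) / 10.5, 1e-3)
  expect_lt(abs(cf[["tau1"]] + 0.005) / 0.005, 1e-3)
  expect_lt(abs(cf[["tau2"]] + 0.8) / 0.8, 1e-3)
  expect_lt(m$rms, 1e-4)
  expect_equal(predict(m, t = 0), 0, tolerance = 1e-9)
})

test_that("the second-order family nests the first order", {
  t <- seq(0, 6, by = 0.02)
  v <- 9.5 * (1 - exp(-t / 1.1))
  m1 <- fit_first_order(t, v, "max")
  m2 <- fit_second_order(t, v)
  expect_lte(m2$rms, m1$rms + 1e-6)
})

test_that("velocity_model dispatches formula and series interfaces alike", {
  t <- seq(0, 6, by = 0.02)
  d <- data.frame(t = t, v = 8 * (1 - exp(-t / 1.4)))
  mf <- velocity_model(v ~ t, d, order = 1)
  mx <- velocity_model(t = d$t, v = d$v, order = 1)
  expect_equal(coef(mf), coef(mx))
  expect_equal(residuals(mf), d$v - fitted(mf))
  expect_error(velocity_model(order = 1), "supply")
})

test_that("mechanical profile reproduces its closed-form parameters", {
  t <- seq(0, 7, by = 0.02)
  v <- 10.5 * (exp(-0.005 * t) - exp(-0.8 * t))
  m <- fit_second_order(t, v)
  prof <- mechanical_profile(m, mass = 75)
  cf <- coef(m)
  # f0 = a (tau1 - tau2); apex time and velocity from the closed form
  expect_equal(prof$f0, cf[["a"]] * (cf[["tau1"]] - cf[["tau2"]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(prof$f0, 8.3475, tolerance = 1e-3)
  t_star <- log(cf[["tau1"]] / cf[["tau2"]]) / (cf[["tau2"]] - cf[["tau1"]])
  expect_equal(prof$t_apex, t_star, tolerance = 1e-9)
  expect_equal(prof$v0, 10.107, tolerance = 1e-3)
  # pmax against a dense-grid oracle over P(t) = v a
  s <- seq(0, t_star, length.out = 200001L)
  p_oracle <- max(predict(m, t = s) * predict(m, t = s, type = "acceleration"))
  expect_equal(prof$pmax, p_oracle, tolerance = 1e-6)
  expect_equal(prof$pmax, 21.6, tolerance = 0.01)
})

test_that("force and power scale with mass, per-mass parameters do not", {
  t <- seq(0, 6, by = 0.02)
  v <- 10.5 * (exp(-0.005 * t) - exp(-0.8 * t))
  m <- fit_second_order(t, v)
  p1 <- mechanical_profile(m, mass = 70)
  p2 <- mechanical_profile(m, mass = 140)
  expect_equal(p2$F_mdl, 2 * p1$F_mdl)
  expect_equal(p2$P_mdl, 2 * p1$P_mdl)
  expect_equal(p2$f0, p1$f0)
  expect_equal(p2$pmax, p1$pmax)
  expect_equal(p1$F_mdl, 70 * p1$a_mdl)
  expect_error(mechanical_profile(m, mass = -1), "mass")
})

test_that("first-order F-V curves are exactly linear, second-order are not", {
  t <- seq(0, 6, by = 0.02)
  m1 <- fit_first_order(t, 10 * (1 - exp(-t / 1.2)), "max")
  pr1 <- mechanical_profile(m1, mass = 75)
  cur1 <- fv_pv_curves(pr1)
  cf <- coef(m1)
  line <- (cf[["vmax"]] - cur1$v) / cf[["tau"]]
  expect_lt(max(abs(cur1$f - line)), 1e-9)
  expect_equal(cur1$p[1L], 0)  # P(0) = 0

  m2 <- fit_second_order(t, 10.5 * (exp(-0.1 * t) - exp(-0.9 * t)))
  cur2 <- fv_pv_curves(mechanical_profile(m2, mass = 75))
  slope <- diff(cur2$f) / diff(cur2$v)
  expect_gt(diff(range(slope)), 1e-3)  # curvature present
})

test_that("alternative power definition multiplies force by acceleration", {
  t <- seq(0, 6, by = 0.02)
  m <- fit_second_order(t, 10.5 * (exp(-0.005 * t) - exp(-0.8 * t)))
  pv <- mechanical_profile(m, mass = 75)
  pa <- mechanical_profile(m, mass = 75, power = "force_acceleration")
  expect_equal(pv$P_mdl, pv$F_mdl * pv$v_mdl)
  expect_equal(pa$P_mdl, pa$F_mdl * pa$a_mdl)
})
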