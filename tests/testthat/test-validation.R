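test_that("resampling follows the stated decimation and interpolation rules", {
  est <- list(t = (0:10) / 200, v = 1:11)
  gnss <- gnss_series((0:5) / 10, c(0, 1, 2, 3, 4, 5))
  rs <- resample_for_comparison(est, gnss)
  # 200 Hz -> 50 Hz: first sample, then every fifth counted inclusively
  expect_length(rs$est$v, 3L)
  expect_equal(rs$est$v, c(1, 5, 9))
  expect_equal(diff(rs$est$t), rep(0.02, 2), tolerance = 1e-12)
  # a linear ramp through the GNSS samples interpolates exactly
  expect_equal(rs$gnss$v, rs$gnss$t * 10, tolerance = 1e-12)
  # no extrapolation beyond the last GNSS sample
  expect_lte(max(rs$gnss$t), 0.5 + 1e-12)

  cst <- resample_for_comparison(list(t = (0:20) / 200, v = rep(4, 21)),
                                 gnss_series((0:3) / 10, rep(4, 4)))
  expect_true(all(cst$est$v == 4))
  expect_true(all(cst$gnss$v == 4))
})

test_that("velocity error normalizes by the reference maximum", {
  expect_equal(velocity_error(c(2, 4), c(1, 3)), 25)
  expect_equal(velocity_error(c(1, 2, 3), c(1, 2, 3)), 0)
  v <- c(2, 5, 10, 7)
  expect_equal(velocity_error(v, v + 0.1 * max(v)), 10, tolerance = 1e-12)
  # scale invariance
  set.seed(2)
  a <- runif(50, 1, 9); b <- a + rnorm(50, sd = 0.3)
  expect_equal(velocity_error(a, b), velocity_error(3 * a, 3 * b),
               tolerance = 1e-12)
  expect_error(velocity_error(rep(0, 3), rep(0, 3)), "positive")
})

test_that("fit error is the unnormalized RMS and links to the percentage", {
  expect_equal(fit_error(c(1, 2), c(1, 2)), 0)
  expect_equal(fit_error(c(1, 2, 3), c(2, 3, 4)), 1)
  set.seed(4)
  a <- runif(30, 1, 9); b <- a + rnorm(30)
  expect_equal(fit_error(a, b), velocity_error(a, b) * max(a) / 100,
               tolerance = 1e-12)
})

test_that("duration error is a signed percentage of the reference", {
  expect_equal(duration_error(8.0, 8.4), -5.0)
  expect_equal(duration_error(7.2, 7.2), 0)
  expect_equal(duration_error(6, 0), 100)
  expect_error(duration_error(0, 1), "T_ref")
})

test_that("error summaries use linear-interpolation percentiles", {
  s <- summarize_errors(c(1, 2, 3))
  expect_equal(s$median, 2)
  s4 <- summarize_errors(c(1, 2, 3, 4))
  expect_equal(s4$median, 2.5)
  expect_equal(c(s4$q25, s4$q75), c(1.75, 3.25))
  s1 <- summarize_errors(5)
  expect_equal(c(s1$q25, s1$median, s1$q75), c(5, 5, 5))
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("Bland-Altman reproduces hand-computed limits", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  bac <- bland_altman(x, x - 2)
  expect_equal(bac$bias, 2)
  expect_equal(bac$loa, c(2, 2))
  ba <- bland_altman(c(0, 2), c(1, 1))   # differences -1, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96 * sqrt(2), 1.96 * sqrt(2)))
  # shifting both series leaves bias and limits unchanged
  set.seed(6)
  a <- rnorm(20); b <- a + rnorm(20)
  ba1 <- bland_altman(a, b); ba2 <- bland_altman(a + 7, b + 7)
  expect_equal(ba1$bias, ba2$bias)
  expect_equal(ba1$loa, ba2$loa)
  expect_true(ba1$loa[1L] <= ba1$bias && ba1$bias <= ba1$loa[2L])
})

test_that("Lin's ccc matches population-moment closed forms", {
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7)
  x <- c(-2, 0, 2)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(x, -x)$ccc, -1)
  set.seed(12)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40, sd = 0.4)
  cc <- lin_ccc(a, b)
  expect_equal(cc$ccc, lin_ccc(b, a)$ccc)           # symmetry
  expect_lte(abs(cc$ccc), 1)
  expect_lte(abs(cc$ccc), abs(cor(a, b)) + 1e-12)   # bias factor <= 1
  expect_true(cc$ci95[1L] <= cc$ccc && cc$ccc <= cc$ci95[2L])
  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), "variance")
})
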