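# The shared one-dimensional linear Kalman filter.  Both pipeline passes
# (sprint detection and GNSS-IMU fusion) use the same constant-velocity
# process driven by the global-frame horizontal acceleration, with the GNSS
# ground speed as the scalar measurement:
#
#   prediction:  v(n|n-1) = v(n-1) + dt * a_GFx(n-1),   p(n|n-1) = p(n-1) + mu * dt^2
#   update:      K = p(n|n-1) / (p(n|n-1) + eta)
#                v(n|n)   = v(n|n-1) + K (z(n) - v(n|n-1))
#                p(n|n)   = (1 - K) p(n|n-1)
#
# mu is the accelerometer (process) noise variance and enters the
# covariance propagation scaled by the squared integration step; eta is the
# GNSS (measurement) noise variance.  A measurement of exactly zero means
# "no measurement": the prediction runs without update (this is also how
# zero-padded upsampling marks the empty grid slots, so a genuine standstill
# reading never corrects the filter).

#' One-dimensional Kalman prediction and update steps
#'
#' @param v_prev,p_prev Prior state mean (m/s) and variance ((m/s)^2).
#' @param a Horizontal acceleration driving the prediction, m/s^2.
#' @param dt Integration step, s.
#' @param mu Process (accelerometer) noise variance, (m/s^2)^2.
#' @param v_pred,p_pred Predicted state mean and variance.
#' @param z Measurement (GNSS ground speed), m/s.
#' @param eta Measurement (GNSS) noise variance, (m/s)^2.
#' @return `kalman_predict()`: list `(v, p)`; `kalman_update()`: list
#'   `(v, p, K)`.
#' @examples
#' kalman_predict(5, 0.01, a = 2, dt = 0.005, mu = 0.4) # v = 5.01
#' kalman_update(5, 0.04, z = 6, eta = 0.01)            # K = 0.8, v = 5.8
#' @export
kalman_predict <- function(v_prev, p_prev, a, dt, mu) {
  list(v = v_prev + dt * a, p = p_prev + mu * dt^2)
}

#' @rdname kalman_predict
#' @export
kalman_update <- function(v_pred, p_pred, z, eta) {
  K <- p_pred / (p_pred + eta)
  list(v = v_pred + K * (z - v_pred), p = (1 - K) * p_pred, K = K)
}

#' Run the Kalman filter over an acceleration series
#'
#' Predicts at every sample of the (typically 200 Hz) acceleration grid and
#' updates only at samples carrying a nonzero measurement.  Sparse
#' measurements given as `(time, value)` pairs are placed at their nearest
#' grid instants (see [zero_pad_upsample()]); alternatively `meas` may be a
#' full-length vector with zeros marking "no measurement".
#'
#' @param t Time grid, s (strictly increasing).
#' @param a Acceleration at each grid sample, m/s^2.
#' @param meas Either a list/data.frame with elements `t` and `v` (sparse
#'   measurements), a full-length numeric vector, or `NULL` for pure
#'   strapdown prediction.
#' @param mu Process noise variance, (m/s^2)^2.
#' @param eta Measurement noise variance, (m/s)^2.
#' @param v0 Initial velocity, m/s (sprint start: 0).
#' @param p0 Initial variance, (m/s)^2; defaults to `eta` (uncertainty of
#'   the order of one measurement).
#' @return An object of class `kalman_run`: list with `t`, `v_est`, `p`,
#'   logical `updated`, and `K` (gain at each update instant, `NA`
#'   elsewhere).
#' @export
kalman_run <- function(t, a, meas = NULL, mu = 0.4, eta = 0.01,
                       v0 = 0, p0 = eta) {
  n <- length(t)
  if (n == 0L) stop("kalman_run: empty acceleration series")
  if (length(a) != n) stop("kalman_run: t and a lengths differ")
  z <- numeric(n)
  if (!is.null(meas)) {
    if (is.list(meas)) {
      if (any(meas$t < t[1L] - 1e-9 | meas$t > t[n] + 1e-9))
        stop("kalman_run: measurement times outside the acceleration span")
      idx <- nearest_grid_index(meas$t, t)
      z[idx] <- meas$v
    } else {
      if (length(meas) != n)
        stop("kalman_run: measurement vector length differs from grid")
      z <- meas
    }
  }
  v <- numeric(n); p <- numeric(n); K <- rep(NA_real_, n)
  upd <- logical(n)
  v[1L] <- v0; p[1L] <- p0
  for (i in seq_len(n - 1L) + 1L) {
    dt <- t[i] - t[i - 1L]
    vp <- v[i - 1L] + dt * a[i - 1L]
    pp <- p[i - 1L] + mu * dt^2
    if (z[i] != 0) {
      k <- pp / (pp + eta)
      v[i] <- vp + k * (z[i] - vp)
      p[i] <- (1 - k) * pp
      K[i] <- k
      upd[i] <- TRUE
    } else {
      v[i] <- vp
      p[i] <- pp
    }
  }
  structure(list(t = t, v_est = v, p = p, K = K, updated = upd,
                 mu = mu, eta = eta),
            class = "kalman_run")
}

# nearest index of each time in `times` on grid `t` (assumed near-uniform)
nearest_grid_index <- function(times, t) {
  dt <- if (length(t) > 1L) stats::median(diff(t)) else 1
  idx <- round((times - t[1L]) / dt) + 1L
  pmin(pmax(idx, 1L), length(t))
}

#' @export
print.kalman_run <- function(x, ...) {
  cat(sprintf("Kalman run: %d samples, %d updates, v in [%.2f, %.2f] m/s\n",
              length(x$t), sum(x$updated), min(x$v_est), max(x$v_est)))
  invisible(x)
}
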