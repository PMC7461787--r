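# Orientation estimation: initial attitude from the static window, a
# gradient-descent (accelerometer-corrected) quaternion filter, and the
# rotation of the accelerometer signal into the sprint-aligned global frame
# with gravity removed.
#
# Frame convention: global X = direction of progression (defined anew for
# every sprint by the mounting orientation at standstill), Y = vertical,
# Z = lateral.  q maps sensor-frame coordinates to global-frame coordinates,
# a_GF = q (x) [0 a_SF] (x) q*.

#' Initial orientation from the static window
#'
#' Returns the minimal rotation mapping the window-mean accelerometer vector
#' (which at standstill is the gravity reaction) onto the global vertical
#' `(0, g, 0)`.  The minimal-rotation construction fixes the heading: the
#' rotation axis is orthogonal to both vectors, so the sensor's forward
#' mounting axis projects onto the global +X axis.
#'
#' @param static_acc Mean specific-force 3-vector over the static window,
#'   m/s^2.  Its norm must lie within 20% of g, otherwise no usable static
#'   period was found.
#' @return A unit quaternion (length-4 numeric, scalar first).
#' @export
initial_orientation <- function(static_acc) {
  nrm <- sqrt(sum(static_acc^2))
  if (abs(nrm - .G) > 0.2 * .G)
    stop("initial_orientation: no static period (|acc| = ",
         signif(nrm, 4), " m/s^2, expected ~g)")
  quat_between(static_acc, c(0, 1, 0))
}

#' Locate the quietest static window before the sprint
#'
#' The initial attitude must come from a window of genuine standstill.  The
#' GNSS-detected start `t_s` can fall after true motion onset (the receiver
#' responds with a lag), so a window simply ending at `t_s` may leak sprint
#' motion into the gravity reference.  Instead, candidate windows of length
#' `len` are slid through `[lo, t_s]` and the one minimizing the combined
#' quiescence metric `sd(|acc|)/g + sd(|gyro|)` is selected (ties toward
#' the latest window).
#'
#' @param imu An [imu_recording()].
#' @param lo Earliest admissible window start (the coarse window start), s.
#' @param t_s Detected sprint start, s.
#' @param len Window length, s.
#' @return Length-2 numeric `c(start, end)` of the chosen window.
#' @export
find_static_window <- function(imu, lo, t_s, len = 1.0) {
  lo <- max(lo, imu$t[1L])
  ends <- seq(lo + len, t_s, by = 0.05)
  if (!length(ends)) {
    return(c(max(imu$t[1L], t_s - len), t_s))
  }
  acc_n <- sqrt(rowSums(imu$acc^2))
  gyr_n <- sqrt(rowSums(imu$gyr^2))
  score <- vapply(ends, function(e) {
    i <- imu$t >= e - len & imu$t <= e
    if (sum(i) < 2L) return(Inf)
    stats::sd(acc_n[i]) / .G + stats::sd(gyr_n[i])
  }, numeric(1L))
  best <- which(score <= min(score) + 1e-12)
  e <- ends[best[length(best)]]
  c(e - len, e)
}

#' Gradient-descent orientation filter
#'
#' Tracks the sensor-to-global quaternion through the sprint.  Each step
#' propagates the attitude with the exact quaternion exponential of the
#' gyroscope increment, then (on quasi-static samples) applies one
#' normalized gradient-descent correction of gain `beta` toward the
#' orientation whose predicted gravity direction matches the measured
#' accelerometer direction, and renormalizes.
#'
#' The accelerometer carries attitude information only when the specific
#' force is close to gravity; during the high-acceleration phase of a sprint
#' the apparent gravity is tilted by atan(a/g) and an unconditional
#' correction would drag the attitude toward it.  The correction is
#' therefore gated: it is applied only when the accelerometer norm is within
#' `acc_gate` (fractional) of g and the gyroscope norm is below
#' `gyro_gate`.  Between corrections the attitude is pure strapdown
#' gyroscope integration.
#'
#' @param imu An [imu_recording()].
#' @param q0 Initial unit quaternion, typically from [initial_orientation()].
#' @param beta Gradient-descent gain, rad/s (>= 0; 0 disables correction).
#' @param acc_gate Fractional tolerance on |acc| around g for the
#'   correction gate.
#' @param gyro_gate Gyroscope-norm threshold (rad/s) for the correction
#'   gate.
#' @return An object of class `quaternion_series`: list with `t` and an
#'   n x 4 matrix `q` of unit quaternions (one per IMU sample; the first row
#'   is `q0`).
#' @export
run_orientation_filter <- function(imu, q0, beta = 0.1, acc_gate = 0.03,
                                   gyro_gate = 0.05) {
  if (beta < 0) stop("run_orientation_filter: beta must be >= 0")
  n <- length(imu$t)
  if (n == 0L) stop("run_orientation_filter: empty IMU recording")
  Q <- matrix(0, n, 4L)
  q <- quat_normalize(q0)
  Q[1L, ] <- q
  if (n == 1L) return(structure(list(t = imu$t, q = Q),
                                class = "quaternion_series"))
  acc_norm <- sqrt(rowSums(imu$acc^2))
  gyr_norm <- sqrt(rowSums(imu$gyr^2))
  gate <- abs(acc_norm - .G) <= acc_gate * .G & gyr_norm <= gyro_gate
  for (i in 2:n) {
    dt <- imu$t[i] - imu$t[i - 1L]
    # midpoint (trapezoidal) rate over the step: a left-rectangle sample
    # leaves an attitude error in phase with oscillatory motion, which
    # rectifies into a DC bias of the rotated acceleration
    w <- (imu$gyr[i - 1L, ] + imu$gyr[i, ]) / 2
    ang <- sqrt(sum(w^2)) * dt
    if (ang > 0) q <- quat_multiply(q, quat_axis_angle(w, ang))
    if (beta > 0 && gate[i]) {
      g_step <- gravity_gradient(q, imu$acc[i, ] / acc_norm[i])
      gn <- sqrt(sum(g_step^2))
      if (gn > 0) q <- q - beta * dt * g_step / gn
    }
    q <- quat_normalize(q)
    Q[i, ] <- q
  }
  structure(list(t = imu$t, q = Q), class = "quaternion_series")
}

# Gradient (J^T F) of the objective F(q) = R(q)^T e_y - a_hat, the mismatch
# between the gravity direction predicted in the sensor frame and the
# normalized accelerometer measurement.
gravity_gradient <- function(q, a_hat) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  F1 <- 2 * (x * y + w * z) - a_hat[1L]
  F2 <- 1 - 2 * x^2 - 2 * z^2 - a_hat[2L]
  F3 <- 2 * (y * z - w * x) - a_hat[3L]
  c(2 * z * F1 - 2 * x * F3,
    2 * y * F1 - 4 * x * F2 - 2 * w * F3,
    2 * x * F1 + 2 * z * F3,
    2 * w * F1 - 4 * z * F2 + 2 * y * F3)
}

#' @export
print.quaternion_series <- function(x, ...) {
  cat(sprintf("Quaternion series: %d samples, %.2f-%.2f s\n",
              length(x$t), x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' Express acceleration in the global frame
#'
#' Rotates every accelerometer sample by its quaternion, subtracts gravity
#' `(0, g, 0)`, and extracts the component along the direction of
#' progression (`a_GFx`).
#'
#' @param imu An [imu_recording()].
#' @param quats A `quaternion_series` from [run_orientation_filter()], one
#'   quaternion per IMU sample.
#' @return An object of class `global_acceleration`: list with `t`, the
#'   n x 3 matrix `a_gf` (gravity removed), and the vector `a_gfx`.
#' @export
to_global_acceleration <- function(imu, quats) {
  if (length(imu$t) != nrow(quats$q))
    stop("to_global_acceleration: IMU and quaternion series lengths differ")
  a_gf <- quat_rotate_rows(quats$q, imu$acc)
  a_gf[, 2L] <- a_gf[, 2L] - .G
  structure(list(t = imu$t, a_gf = a_gf, a_gfx = a_gf[, 1L]),
            class = "global_acceleration")
}

#' @export
print.global_acceleration <- function(x, ...) {
  cat(sprintf("Global acceleration: %d samples, a_GFx in [%.2f, %.2f] m/s^2\n",
              length(x$t), min(x$a_gfx), max(x$a_gfx)))
  invisible(x)
}
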