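# Phase 1 of the pipeline: precise start detection from the GNSS speed,
# measurement-noise tuning via the exponential-rise check, the
# sprint-detection Kalman pass, and segmentation of the sprint by the
# integrated distance.

#' Detect the precise sprint start
#'
#' Within the manually chosen coarse window, the precise starting time `t_s`
#' is the time of the last GNSS sample at or below the threshold before the
#' first sample (after `coarse_start`) exceeding it, so that the static
#' window still precedes all motion.
#'
#' @param gnss A [gnss_series()].
#' @param coarse_start Start of the coarse window, s.
#' @param threshold Speed threshold, m/s (default 0.3).
#' @return `t_s` in seconds.
#' @export
detect_start <- function(gnss, coarse_start = 0, threshold = 0.3) {
  cand <- which(gnss$t >= coarse_start & gnss$v > threshold)
  if (!length(cand))
    stop("detect_start: no sprint found (threshold ", threshold,
         " m/s never exceeded after ", coarse_start, " s)")
  first_over <- cand[1L]
  if (first_over == 1L) return(gnss$t[1L])
  below <- which(gnss$v[seq_len(first_over - 1L)] <= threshold)
  if (!length(below))
    stop("detect_start: no sample at or below the threshold precedes motion")
  gnss$t[max(below)]
}

#' Zero-padded upsampling of the GNSS speed
#'
#' Places each GNSS sample at its nearest instant of the target grid and
#' fills every other grid slot with zero, the filter's "no measurement"
#' marker.  Used to bring the 10 Hz ground speed onto the 200 Hz
#' acceleration grid.
#'
#' @param gnss A [gnss_series()].
#' @param target_fs Target sampling frequency, Hz (a multiple of the GNSS
#'   rate).
#' @param grid_t Optional explicit target grid (overrides `target_fs`);
#'   samples outside the grid span are dropped.
#' @return A list with `t` (the target grid) and `v` (zero-padded speeds).
#' @export
zero_pad_upsample <- function(gnss, target_fs = 200, grid_t = NULL) {
  if (is.null(grid_t)) {
    n <- round((gnss$t[length(gnss$t)] - gnss$t[1L]) * target_fs)
    grid_t <- gnss$t[1L] + (0:n) / target_fs
  }
  keep <- gnss$t >= grid_t[1L] - 1e-9 & gnss$t <= grid_t[length(grid_t)] + 1e-9
  z <- numeric(length(grid_t))
  if (any(keep)) {
    idx <- nearest_grid_index(gnss$t[keep], grid_t)
    z[idx] <- gnss$v[keep]
  }
  list(t = grid_t, v = z)
}

#' Tune the GNSS measurement noise from the exponential rise
#'
#' The GNSS speed deficit `vmax_obs - v(t)` of an ideal maximal sprint
#' decays as `vmax * exp(-t / tau)`.  The deficit of the segment is fitted
#' by least squares over `tau` (bounded to \[0.05, 30\] s); if the fit is
#' good (R-squared above `r2_threshold`, default 0.91) the GNSS stream is
#' trusted and `eta` keeps its base value, otherwise `eta` is escalated by
#' an order of magnitude.  Segments with fewer than 5 positive samples skip
#' the fit and take the conservative escalated value.
#'
#' @param gnss A [gnss_series()] restricted to the sprint segment (time
#'   origin at the segment start).
#' @param config A [session_config()] supplying `eta`, `eta_escalated` and
#'   `r2_threshold`.
#' @return An object of class `eta_tune`: list with `r2`, `eta_chosen`,
#'   `vmax_obs`, `tau_hat`.
#' @export
tune_eta <- function(gnss, config = session_config()) {
  pos <- gnss$v > 0
  if (sum(pos) < 5L) {
    return(structure(list(r2 = NA_real_, eta_chosen = config$eta_escalated,
                          vmax_obs = if (any(pos)) max(gnss$v) else NA_real_,
                          tau_hat = NA_real_),
                     class = "eta_tune"))
  }
  tt <- gnss$t[pos] - gnss$t[pos][1L]
  vmax_obs <- max(gnss$v[pos])
  y <- vmax_obs - gnss$v[pos]
  sse <- function(tau) sum((y - vmax_obs * exp(-tt / tau))^2)
  tau_hat <- stats::optimize(sse, c(0.05, 30))$minimum
  ss_res <- sse(tau_hat)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  eta_chosen <- if (!is.na(r2) && r2 > config$r2_threshold) config$eta else
    config$eta_escalated
  structure(list(r2 = r2, eta_chosen = eta_chosen, vmax_obs = vmax_obs,
                 tau_hat = tau_hat),
            class = "eta_tune")
}

#' @export
print.eta_tune <- function(x, ...) {
  cat(sprintf("GNSS exponential-rise check: R2 = %.3f, tau = %.3f s, vmax = %.2f m/s -> eta = %g\n",
              x$r2, x$tau_hat, x$vmax_obs, x$eta_chosen))
  invisible(x)
}

#' Integrate a velocity series into a distance profile
#'
#' Cumulative trapezoidal integration from the series start; the first
#' value is 0.
#'
#' @param t Time grid, s.
#' @param v Velocity, m/s.
#' @return Distance series in metres, same length as `t`.
#' @export
integrate_velocity <- function(t, v) cum_trapz(t, v)

#' Segment the sprint precisely (phase-1 Kalman pass)
#'
#' Runs start detection, the exponential-rise tuning of `eta`, the
#' sprint-detection Kalman filter, and distance integration.  The ending
#' time `t_e` is the first instant at which the integrated distance reaches
#' the sprint distance `D`, located with linear interpolation between the
#' bracketing samples.
#'
#' @param accel A `global_acceleration` from [to_global_acceleration()].
#' @param gnss A [gnss_series()].
#' @param config A [session_config()] (supplies `D`, thresholds and filter
#'   noise).
#' @param t_s Pre-detected starting time, s; detected from `gnss` with
#'   [detect_start()] when `NULL`.
#' @return An object of class `sprint_window`: list with `t_s`, `t_e`,
#'   `t_d`, `D`, the phase-1 `eta_tune`, `kalman_run` and distance series
#'   `x`.
#' @export
segment_sprint <- function(accel, gnss, config, t_s = NULL) {
  if (is.null(t_s))
    t_s <- detect_start(gnss, config$coarse_start, config$start_threshold)
  seg <- gnss$t >= t_s
  tune <- tune_eta(gnss_subset(gnss, seg), config)
  sel <- accel$t >= t_s
  if (!any(sel)) stop("segment_sprint: no acceleration samples after t_s")
  t <- accel$t[sel]
  z <- zero_pad_upsample(gnss_subset(gnss, seg), grid_t = t)$v
  run <- kalman_run(t, accel$a_gfx[sel], z, mu = config$mu,
                    eta = tune$eta_chosen)
  x <- integrate_velocity(t, run$v_est)
  t_e <- distance_crossing_time(t, x, config$distance)
  if (is.na(t_e))
    stop("segment_sprint: sprint incomplete, integrated distance reached ",
         signif(max(x), 4), " m of ", config$distance, " m")
  structure(list(t_s = t_s, t_e = t_e, t_d = t_e - t_s, D = config$distance,
                 tune = tune, run = run, x = x),
            class = "sprint_window")
}

gnss_subset <- function(gnss, keep) {
  gnss_series(gnss$t[keep], gnss$v[keep], fs = gnss$fs)
}

#' @export
print.sprint_window <- function(x, ...) {
  cat(sprintf("Sprint window: t_s = %.3f s, t_e = %.3f s (t_d = %.3f s over %g m)\n",
              x$t_s, x$t_e, x$t_d, x$D))
  print(x$tune)
  invisible(x)
}
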