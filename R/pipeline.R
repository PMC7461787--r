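# End-to-end orchestration: run the estimator, fit the profile models, and
# (when reference instruments are available) compute the validation errors.

#' Analyze a sprint end to end
#'
#' Runs [sprint_velocity()], fits the three exponential profile models to
#' the fused estimate (first order anchored at the maximum and at the end
#' velocity, and second order), derives the mechanical profile from the
#' second-order fit, and, when a radar reference and photocell times are
#' available, computes the validation errors: normalized velocity RMS
#' for the fused estimate, the raw GNSS speed and the strapdown (IMU-only)
#' integration, the fit RMS of each model against both references, and the
#' signed duration error against the photocells.
#'
#' Alignment convention: the radar series starts at its trigger (motion
#' onset) and the estimate at the detected start `t_s`; both are compared
#' from their respective origins, truncated to the shorter series.
#'
#' @param imu An [imu_recording()].
#' @param gnss A [gnss_series()].
#' @param config A [session_config()].
#' @param radar Optional [radar_series()] (time origin at its trigger).
#' @return An object of class `sprint_report`.
#' @export
analyze_sprint <- function(imu, gnss, config, radar = NULL) {
  fit <- sprint_velocity(imu, gnss, config)
  est <- fit$estimate
  models <- list(
    order1_max = fit_first_order(est$t, est$v_est, "max"),
    order1_end = fit_first_order(est$t, est$v_est, "end"),
    order2 = fit_second_order(est$t, est$v_est))
  profile <- mechanical_profile(models$order2, config$mass)
  errors <- NULL
  if (!is.null(radar)) {
    errors <- validation_errors(fit, gnss, radar, config, models)
  }
  structure(list(fit = fit, models = models, profile = profile,
                 errors = errors, config = config),
            class = "sprint_report")
}

#' @rdname analyze_sprint
#' @param session A `sprint_session` from [sprint_session()].
#' @export
analyze_session <- function(session) {
  analyze_sprint(session$imu, session$gnss, session$config, session$radar)
}

validation_errors <- function(fit, gnss, radar, config, models) {
  est <- fit$estimate
  rs <- resample_for_comparison(list(t = est$t, v = est$v_est),
                                gnss_retimed(gnss, fit$t_s_raw))
  n_est <- min(length(rs$est$v), length(radar$v))
  rms_est <- velocity_error(radar$v[seq_len(n_est)], rs$est$v[seq_len(n_est)])
  n_g <- min(length(rs$gnss$v), length(radar$v))
  rms_gnss <- velocity_error(radar$v[seq_len(n_g)], rs$gnss$v[seq_len(n_g)])
  sd_est <- strapdown_velocity(fit$accel, fit$window, config)
  sd50 <- sd_est$v_est[seq(1L, length(sd_est$t), by = 4L)]
  n_s <- min(length(sd50), length(radar$v))
  rms_imu <- velocity_error(radar$v[seq_len(n_s)], sd50[seq_len(n_s)])
  # fit errors on the common radar grid (time from sprint start)
  tau <- radar$t[seq_len(n_est)]
  fit_rms_radar <- vapply(models, function(m)
    fit_error(radar$v[seq_len(n_est)], predict(m, t = tau)), numeric(1L))
  eps_t <- NULL
  if (!is.null(config$photocell_times)) {
    T_ref <- diff(config$photocell_times)
    eps_t <- duration_error(T_ref, fit$T_est)
  }
  list(velocity_rms_pct = rms_est, gnss_rms_pct = rms_gnss,
       strapdown_rms_pct = rms_imu, fit_rms_radar = fit_rms_radar,
       duration_err_pct = eps_t,
       v_max_radar = max(radar$v), v_max_est = fit$v_max)
}

gnss_retimed <- function(gnss, t_s) {
  keep <- gnss$t >= t_s
  gnss_series(gnss$t[keep] - t_s, gnss$v[keep], fs = gnss$fs)
}

#' @export
print.sprint_report <- function(x, ...) {
  print(x$fit)
  for (m in x$models) print(m)
  print(x$profile)
  if (!is.null(x$errors)) {
    e <- x$errors
    cat(sprintf("Validation: velocity RMS %.2f%% (GNSS %.2f%%, strapdown %.2f%%)\n",
                e$velocity_rms_pct, e$gnss_rms_pct, e$strapdown_rms_pct))
    if (!is.null(e$duration_err_pct))
      cat(sprintf("  duration error %.2f%% (photocell reference)\n",
                  e$duration_err_pct))
    cat(sprintf("  fit RMS vs radar (m/s): %s\n",
                paste(sprintf("%s %.3f", names(e$fit_rms_radar),
                              e$fit_rms_radar), collapse = ", ")))
  }
  invisible(x)
}

#' Run a cohort of synthetic sessions
#'
#' Simulates and analyzes `length(seeds)` sessions per distance and returns
#' one row of error metrics per trial -- the synthetic analogue of a
#' multi-athlete validation campaign.
#'
#' @param distances Sprint distances, m.
#' @param seeds Noise seeds; seed `seeds[i]` is paired with distance
#'   `distances[i]` (vectors are recycled to equal length).
#' @param noise A [noise_model()] template (its seed is overridden
#'   per trial).
#' @param ... Passed to [sprint_session()].
#' @return A data frame with one row per trial: `distance`, `seed`,
#'   velocity RMS percentages for the fused estimate / GNSS / strapdown,
#'   duration error, maxima and profile parameters.
#' @export
run_cohort <- function(distances = rep(c(30, 40, 60), each = 10),
                       seeds = 0:29, noise = noise_model(), ...) {
  k <- max(length(distances), length(seeds))
  distances <- rep_len(distances, k)
  seeds <- rep_len(seeds, k)
  rows <- lapply(seq_len(k), function(i) {
    ns <- noise
    ns$seed <- as.integer(seeds[i])
    ses <- sprint_session(distance = distances[i], noise = ns, ...)
    rep <- analyze_session(ses)
    e <- rep$errors
    data.frame(distance = distances[i], seed = seeds[i],
               rms_est = e$velocity_rms_pct, rms_gnss = e$gnss_rms_pct,
               rms_imu = e$strapdown_rms_pct,
               duration_err = e$duration_err_pct,
               v_max_est = e$v_max_est, v_max_radar = e$v_max_radar,
               v0 = rep$profile$v0, f0 = rep$profile$f0,
               pmax = rep$profile$pmax,
               T_est = rep$fit$T_est,
               T_ref = diff(ses$config$photocell_times))
  })
  do.call(rbind, rows)
}

#' Sensitivity of the velocity error to the start threshold
#'
#' Re-runs the pipeline on one session for each candidate start-detection
#' threshold and reports the resulting normalized velocity RMS against the
#' radar.
#'
#' @param session A `sprint_session`.
#' @param thresholds Candidate thresholds, m/s.
#' @return Data frame with columns `threshold` and `rms_pct`.
#' @export
sweep_start_threshold <- function(session, thresholds = c(0.1, 0.3, 0.5)) {
  if (!length(thresholds)) stop("sweep_start_threshold: empty threshold list")
  rows <- lapply(thresholds, function(th) {
    cfg <- session$config
    cfg$start_threshold <- th
    rep <- analyze_sprint(session$imu, session$gnss, cfg, session$radar)
    data.frame(threshold = th, rms_pct = rep$errors$velocity_rms_pct)
  })
  do.call(rbind, rows)
}
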