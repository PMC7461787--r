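# Sensor-series containers and the CSV / config dialects.
#
# All on-disk series are plain comma-separated UTF-8 with one header row and
# '.' decimals.  Timestamps are seconds from recording start.  Accelerations
# are m/s^2 (a config flag converts device exports expressed in g), angular
# rates rad/s, speeds m/s.

#' IMU recording container
#'
#' Holds a tri-axial accelerometer + gyroscope recording: specific force in
#' the sensor frame (m/s^2), angular rate (rad/s), and timestamps (s).
#'
#' @param t Numeric vector of timestamps, strictly increasing, seconds.
#' @param acc n x 3 numeric matrix of specific force, m/s^2 (sensor frame).
#' @param gyr n x 3 numeric matrix of angular rate, rad/s (sensor frame).
#' @param fs Sampling frequency in Hz; inferred from the median timestep if
#'   omitted.
#' @return An object of class `imu_recording` with fields `t`, `acc`, `gyr`,
#'   `fs`.
#' @export
imu_recording <- function(t, acc, gyr, fs = NULL) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  if (length(t) != nrow(acc) || length(t) != nrow(gyr))
    stop("imu_recording: t, acc and gyr must have equal lengths")
  if (ncol(acc) != 3L || ncol(gyr) != 3L)
    stop("imu_recording: acc and gyr must have 3 columns")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("imu_recording: timestamps must be strictly increasing")
  if (is.null(fs)) fs <- infer_fs(t)
  if (!is.finite(fs) || fs <= 0) stop("imu_recording: fs must be > 0")
  structure(list(t = as.numeric(t), acc = unname(acc), gyr = unname(gyr),
                 fs = fs),
            class = "imu_recording")
}

#' Scalar ground-speed series (GNSS or radar)
#'
#' @param t Timestamps, seconds, strictly increasing.
#' @param v Ground speed, m/s.  GNSS speeds must be non-negative.
#' @param fs Sampling frequency, Hz; inferred from the median timestep if
#'   omitted.
#' @return An object of class `speed_series` (and `gnss_series` or
#'   `radar_series`).
#' @export
gnss_series <- function(t, v, fs = NULL) {
  if (any(v < 0)) stop("gnss_series: ground speed must be non-negative")
  new_speed_series(t, v, fs, "gnss_series")
}

#' @rdname gnss_series
#' @export
radar_series <- function(t, v, fs = NULL) new_speed_series(t, v, fs, "radar_series")

new_speed_series <- function(t, v, fs, subclass) {
  if (length(t) != length(v)) stop("speed series: t and v lengths differ")
  if (length(t) == 0L) stop("speed series: empty series")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("speed series: timestamps must be strictly increasing")
  if (is.null(fs)) fs <- infer_fs(t)
  if (!is.finite(fs) || fs <= 0) stop("speed series: fs must be > 0")
  structure(list(t = as.numeric(t), v = as.numeric(v), fs = fs),
            class = c(subclass, "speed_series"))
}

infer_fs <- function(t) {
  if (length(t) < 2L) return(NA_real_)
  1 / stats::median(diff(t))
}

#' Session configuration
#'
#' Bundles the per-session constants of the estimation pipeline: sprint
#' distance, athlete mass, the manual coarse window, and the filter tuning
#' constants.  Defaults follow the tuned values of the estimation method
#' (`eta` = 0.01 (m/s)^2, `mu` = 0.4 (m/s^2)^2, start threshold 0.3 m/s,
#' R-squared gate 0.91 with escalation of `eta` to 0.1 on a poor exponential
#' fit).
#'
#' @param distance Sprint distance D in metres (30/40/60 m typical).
#' @param mass Athlete mass in kg.
#' @param coarse_start Start of the manually selected coarse window, s.
#' @param static_window Length of the static period used for the initial
#'   orientation, s.
#' @param start_threshold GNSS speed threshold for precise start detection,
#'   m/s.
#' @param eta Measurement (GNSS) noise variance, (m/s)^2.
#' @param eta_escalated Escalated `eta` used when the exponential fit of the
#'   GNSS rise is poor, (m/s)^2.
#' @param mu Process (accelerometer) noise variance, (m/s^2)^2.
#' @param r2_threshold R-squared above which the GNSS rise counts as
#'   exponential and `eta` is kept at its base value.
#' @param beta Orientation-filter gradient-descent gain, rad/s.
#' @param gnss_lag_max Upper bound for the data-driven GNSS latency
#'   estimate used to time-align the streams before fusion, s (0 disables
#'   the alignment).
#' @param photocell_times Optional length-2 vector of photocell timestamps
#'   (start, end), s, giving the reference duration.
#' @param acc_in_g If `TRUE`, accelerometer CSV columns are in g and are
#'   converted with g = 9.80665 m/s^2 on read.
#' @return An object of class `session_config` (a named list).
#' @export
session_config <- function(distance = 60, mass = 75, coarse_start = 0,
                           static_window = 1.0, start_threshold = 0.3,
                           eta = 0.01, eta_escalated = 0.1, mu = 0.4,
                           r2_threshold = 0.91, beta = 0.1,
                           gnss_lag_max = 1.0,
                           photocell_times = NULL, acc_in_g = FALSE) {
  if (distance <= 0) stop("session_config: distance must be > 0")
  if (mass <= 0) stop("session_config: mass must be > 0")
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("session_config: r2_threshold must lie in (0, 1)")
  if (eta_escalated <= eta)
    stop("session_config: eta_escalated must exceed eta")
  if (eta <= 0 || mu < 0) stop("session_config: eta > 0 and mu >= 0 required")
  structure(list(distance = distance, mass = mass, coarse_start = coarse_start,
                 static_window = static_window,
                 start_threshold = start_threshold, eta = eta,
                 eta_escalated = eta_escalated, mu = mu,
                 r2_threshold = r2_threshold, beta = beta,
                 gnss_lag_max = gnss_lag_max,
                 photocell_times = photocell_times, acc_in_g = acc_in_g),
            class = "session_config")
}

#' Read and write sensor CSV files
#'
#' `read_imu_csv()` expects the header `t,ax,ay,az,gx,gy,gz`;
#' `read_speed_csv()` the header `t,v`.  Sampling frequencies are inferred
#' from the median timestep.  The writers emit full double precision so a
#' write/read round trip is lossless to better than 1e-12.
#'
#' @param path File path.
#' @param acc_in_g If `TRUE`, acceleration columns on disk are in g and are
#'   converted to m/s^2.
#' @param kind `"gnss"` or `"radar"` for speed files.
#' @param imu,series Objects to write.
#' @return `read_imu_csv()` an [imu_recording()]; `read_speed_csv()` a
#'   [gnss_series()] or [radar_series()].  Writers return `path` invisibly.
#' @export
read_imu_csv <- function(path, acc_in_g = FALSE) {
  if (!file.exists(path)) stop("read_imu_csv: file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(d)))
    stop("read_imu_csv: missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  acc <- as.matrix(d[, c("ax", "ay", "az")])
  if (acc_in_g) acc <- acc * .G
  imu_recording(d$t, acc, as.matrix(d[, c("gx", "gy", "gz")]))
}

#' @rdname read_imu_csv
#' @export
write_imu_csv <- function(imu, path) {
  d <- data.frame(t = num_chr(imu$t),
                  ax = num_chr(imu$acc[, 1L]), ay = num_chr(imu$acc[, 2L]),
                  az = num_chr(imu$acc[, 3L]),
                  gx = num_chr(imu$gyr[, 1L]), gy = num_chr(imu$gyr[, 2L]),
                  gz = num_chr(imu$gyr[, 3L]))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_imu_csv
#' @export
read_speed_csv <- function(path, kind = c("gnss", "radar")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_speed_csv: file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("t", "v") %in% names(d)))
    stop("read_speed_csv: header must contain columns t,v")
  if (nrow(d) == 0L) stop("read_speed_csv: empty series in ", path)
  if (kind == "gnss") gnss_series(d$t, d$v) else radar_series(d$t, d$v)
}

#' @rdname read_imu_csv
#' @export
write_speed_csv <- function(series, path) {
  d <- data.frame(t = num_chr(series$t), v = num_chr(series$v))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and save session configuration files
#'
#' Configs are YAML key:value files.  Absent keys take the defaults of
#' [session_config()].
#'
#' @param path File path.
#' @param config A [session_config()] to save.
#' @return `load_config()` returns a [session_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(session_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("load_config: ignoring unknown key(s): ",
            paste(unknown, collapse = ", "))
  vals <- vals[intersect(names(vals), known)]
  if (!is.null(vals$photocell_times))
    vals$photocell_times <- as.numeric(unlist(vals$photocell_times))
  do.call(session_config, vals)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1L))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.session_config <- function(x, ...) {
  cat("Sprint session configuration\n")
  cat(sprintf("  distance: %g m, mass: %g kg\n", x$distance, x$mass))
  cat(sprintf("  coarse window from %g s; static window %g s\n",
              x$coarse_start, x$static_window))
  cat(sprintf("  start threshold %g m/s; eta %g (escalated %g); mu %g; R2 gate %g\n",
              x$start_threshold, x$eta, x$eta_escalated, x$mu, x$r2_threshold))
  if (!is.null(x$photocell_times))
    cat(sprintf("  photocells at %.3f s and %.3f s\n",
                x$photocell_times[1L], x$photocell_times[2L]))
  invisible(x)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording: %d samples at %.6g Hz, %.2f-%.2f s\n",
              length(x$t), x$fs, x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("%s: %d samples at %.6g Hz, peak %.2f m/s\n",
              if (inherits(x, "gnss_series")) "GNSS speed" else "Radar speed",
              length(x$t), x$fs, max(x$v)))
  invisible(x)
}
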