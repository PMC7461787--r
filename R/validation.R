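# Validation statistics: the resampling rules that bring the estimate, the
# GNSS speed and the radar reference onto a common 50 Hz grid, the error
# vectors and their RMS / median / IQR summaries, Bland-Altman limits of
# agreement, and Lin's concordance correlation coefficient.

#' Resample estimate and GNSS speed to the 50 Hz radar grid
#'
#' The 200 Hz estimate is decimated to 50 Hz by keeping the first sample
#' and every fifth sample counted inclusively (index step 4, so the
#' decimated grid is a true 50 Hz grid); the 10 Hz GNSS speed is linearly
#' interpolated onto the 50 Hz grid (no extrapolation beyond its last
#' sample).
#'
#' @param est List/series with `t` and `v` at 200 Hz (e.g. the `t`/`v_est`
#'   of a `velocity_estimate`).
#' @param gnss A [gnss_series()] (10 Hz).
#' @return List with `est` and `gnss`, each a list of `t`, `v` at 50 Hz.
#' @export
resample_for_comparison <- function(est, gnss) {
  if (!length(est$t) || !length(gnss$t))
    stop("resample_for_comparison: empty series")
  keep <- seq(1L, length(est$t), by = 4L)
  grid <- seq(gnss$t[1L], gnss$t[length(gnss$t)], by = 0.02)
  gi <- stats::approx(gnss$t, gnss$v, xout = grid, rule = 1)
  ok <- !is.na(gi$y)
  list(est = list(t = est$t[keep], v = est$v[keep]),
       gnss = list(t = grid[ok], v = gi$y[ok]))
}

#' Velocity, fit and duration error measures
#'
#' `velocity_error()` is the normalized per-sample error
#' \deqn{\varepsilon_v(t) = \frac{v_{ref}(t) - v_{test}(t)}{\max v_{ref}} \times 100\%}
#' summarized as its RMS over the sprint window.  `fit_error()` is the
#' unnormalized RMS of `v_ref - v_fit` in m/s.  `duration_error()` is the
#' signed percentage `(T_ref - T_test)/T_ref * 100` (negative means the
#' duration was overestimated).
#'
#' @param v_ref,v_test,v_fit Speed series on a common grid, m/s.
#' @param T_ref,T_test Durations, s (`T_ref > 0`).
#' @return `velocity_error()` and `duration_error()` percentages,
#'   `fit_error()` m/s.
#' @examples
#' velocity_error(c(2, 4), c(1, 3)) # 25
#' duration_error(8.0, 8.4)         # -5
#' @export
velocity_error <- function(v_ref, v_test) {
  if (length(v_ref) != length(v_test))
    stop("velocity_error: series lengths differ")
  m <- max(v_ref)
  if (m <= 0) stop("velocity_error: max(v_ref) must be positive")
  rms((v_ref - v_test) / m * 100)
}

#' @rdname velocity_error
#' @export
fit_error <- function(v_ref, v_fit) {
  if (length(v_ref) != length(v_fit))
    stop("fit_error: series lengths differ")
  rms(v_ref - v_fit)
}

#' @rdname velocity_error
#' @export
duration_error <- function(T_ref, T_test) {
  if (T_ref <= 0) stop("duration_error: T_ref must be > 0")
  (T_ref - T_test) / T_ref * 100
}

#' Median and interquartile range of per-trial errors
#'
#' Percentiles use the linear-interpolation convention (type 7).
#'
#' @param values Numeric vector of per-trial RMS errors.
#' @return An object of class `error_summary`: list with `median`, `q25`,
#'   `q75` and the input `values`.
#' @export
summarize_errors <- function(values) {
  if (!length(values)) stop("summarize_errors: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2L], q25 = q[1L], q75 = q[3L], values = values),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("median %.3f (IQR %.3f to %.3f), n = %d\n",
              x$median, x$q25, x$q75, length(x$values)))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Mean difference (bias) and 1.96-SD limits of agreement of paired
#' measurements, using the sample (n-1) standard deviation.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 2).
#' @return An object of class `bland_altman`: list with `bias`, `loa`
#'   (lower, upper), `sd`, `mean_xy` and `diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("bland_altman: lengths differ")
  if (length(x) < 2L) stop("bland_altman: need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
                 sd = s, mean_xy = (x + y) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, LoA [%.4f, %.4f] (n = %d)\n",
              x$bias, x$loa[1L], x$loa[2L], length(x$diff)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$mean_xy, x$diff, pch = 20, xlab = "mean of methods",
                 ylab = "difference", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement index penalizing both imprecision and location/scale shift:
#' \deqn{ccc = \frac{2\,s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) moments.  The 95% confidence interval uses the
#' Fisher z-transform with Lin's asymptotic standard error.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 3, nonzero
#'   variance).
#' @return List with `ccc` and `ci95` (length-2 vector).
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc # 4/7
#' @export
lin_ccc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("lin_ccc: lengths differ")
  if (n < 3L) stop("lin_ccc: need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) stop("lin_ccc: zero variance in both series")
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  if (abs(ccc) >= 1 - 1e-12 || abs(r) >= 1 - 1e-12 || sx2 == 0 || sy2 == 0) {
    return(list(ccc = ccc, ci95 = c(ccc, ccc)))
  }
  u <- (mx - my) / (sx2 * sy2)^(1 / 4)
  se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                  2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                  ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
  z <- atanh(ccc)
  list(ccc = ccc, ci95 = tanh(c(z - 1.96 * se_z, z + 1.96 * se_z)))
}
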