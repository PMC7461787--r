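# shared numerical helpers

#' Standard gravity
#'
#' Conventional standard acceleration due to gravity, used throughout for
#' gravity compensation and for converting accelerometer units expressed in g.
#'
#' @return Scalar, 9.80665 m/s^2.
#' @export
standard_gravity <- function() 9.80665

.G <- 9.80665

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Cumulative trapezoidal integral of y(t); first element is 0.
cum_trapz <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 2L) return(rep(0, length(t)))
  c(0, cumsum(diff(t) * (y[-length(y)] + y[-1L]) / 2))
}

rms <- function(x) sqrt(mean(x^2))

# First time at which the cumulative distance series reaches `target`,
# with linear interpolation between the bracketing samples.
# Returns NA_real_ if the target is never reached.
distance_crossing_time <- function(t, x, target) {
  i <- which(x >= target)
  if (!length(i)) return(NA_real_)
  i <- i[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (target - x[i - 1L]) / (x[i] - x[i - 1L]) * (t[i] - t[i - 1L])
}

# format numerics at full double precision for lossless CSV round-trips
num_chr <- function(x) sprintf("%.17g", x)
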