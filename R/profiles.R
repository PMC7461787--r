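# Exponential velocity-profile models and the mechanical (force / power)
# profiles derived from them.
#
# First order:   v(t) = vmax (1 - exp(-t / tau))          -- single free tau,
#                amplitude anchored at the observed maximum or at the end
#                velocity.
# Second order:  v(t) = a exp(tau1 t) - a exp(tau2 t),    tau2 < tau1 <= 0,
#                which can rise and then decay; fitted by bounded
#                Levenberg-Marquardt least squares with multiple starts.
#
# From the best model: F(t) = M a_mdl(t), P(t) = F(t) v(t), and the
# theoretical profile parameters v0 (velocity at zero acceleration),
# f0 (= a_mdl(0), N/kg) and pmax (apex of P/M over the rise).

#' Fit an exponential velocity-profile model
#'
#' `velocity_model()` is the formula front end (`v ~ t`); `fit_first_order()`
#' and `fit_second_order()` take the series directly.  Time is re-origined
#' to the first sample (the sprint start, where `v` is expected to be near
#' zero).
#'
#' For the first-order model the amplitude is fixed at the observed maximum
#' (`anchor = "max"`) or at the end velocity (`anchor = "end"`, the mean of
#' the last 0.1 s), and the single time constant `tau` is fitted by
#' bounded least squares on \[0.05, 30\] s.  The second-order model fits
#' `(a, tau1, tau2)` by bounded Levenberg-Marquardt with a multi-start
#' strategy seeded from the first-order fit (`tau2 = -1/tau_hat`) plus four
#' jittered restarts; the lowest SSE wins, ties broken toward the smaller
#' `|tau1|`.
#'
#' @param formula A formula `v ~ t`.
#' @param data Data frame (or environment) holding the variables.
#' @param order 1 or 2.
#' @param anchor `"max"` or `"end"` (first order only).
#' @param t,v Numeric series (alternative to the formula interface).
#' @return An object of class `velocity_model` with fields `order`,
#'   `anchor` (first order), `coef`, `rms`, `t`, `v`, `fitted`.  Methods:
#'   `coef`, `predict` (velocity or acceleration), `fitted`, `residuals`,
#'   `print`, `summary`, `plot`.
#' @examples
#' t <- seq(0, 6, by = 0.02)
#' v <- 9.5 * (1 - exp(-t / 1.3))
#' m <- velocity_model(v ~ t, order = 1)
#' coef(m) # tau recovered at 1.3
#' @export
velocity_model <- function(formula = NULL, data = NULL, order = 2,
                           anchor = c("max", "end"), t = NULL, v = NULL) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    v <- mf[[1L]]
    t <- mf[[2L]]
  }
  if (is.null(t) || is.null(v))
    stop("velocity_model: supply a formula v ~ t or both t and v")
  if (order == 1) fit_first_order(t, v, anchor) else fit_second_order(t, v)
}

#' @rdname velocity_model
#' @export
fit_first_order <- function(t, v, anchor = c("max", "end")) {
  anchor <- match.arg(anchor)
  stopifnot(length(t) == length(v))
  tt <- t - t[1L]
  A <- if (anchor == "max") max(v) else v_end_of(tt, v)
  if (!is.finite(A) || A <= 0)
    stop("fit_first_order: non-positive anchor velocity")
  sse <- function(tau) sum((v - A * (1 - exp(-tt / tau)))^2)
  opt <- stats::optimize(sse, c(0.05, 30), tol = 1e-10)
  res <- v - A * (1 - exp(-tt / opt$minimum))
  new_velocity_model(order = 1L, anchor = anchor,
                     coef = c(vmax = A, tau = opt$minimum),
                     t = t, tt = tt, v = v)
}

# end velocity: mean of the last 0.1 s of the series (robust to sample noise)
v_end_of <- function(tt, v) {
  mean(v[tt >= tt[length(tt)] - 0.1])
}

#' @rdname velocity_model
#' @export
fit_second_order <- function(t, v) {
  stopifnot(length(t) == length(v))
  if (length(t) < 10L) stop("fit_second_order: need at least 10 samples")
  tt <- t - t[1L]
  f1 <- fit_first_order(t, v, "max")
  tau_hat <- unname(coef(f1)["tau"])
  starts <- list(c(a = max(v), tau1 = -0.01, tau2 = -1 / tau_hat))
  with_seed(42L, {
    for (k in 1:4) {
      j <- exp(stats::rnorm(3L, sd = 0.4))
      starts[[k + 1L]] <- c(a = max(v) * j[1L], tau1 = -0.01 * j[2L],
                            tau2 = -j[3L] / tau_hat)
    }
  })
  lower <- c(a = 1e-6, tau1 = -5, tau2 = -30)
  upper <- c(a = 1e3, tau1 = 0, tau2 = -1e-6)
  cands <- list()
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a * (exp(tau1 * tt) - exp(tau2 * tt)),
                        data = data.frame(v = v, tt = tt),
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf[["tau2"]] >= cf[["tau1"]]) next
    cands[[length(cands) + 1L]] <-
      list(coef = cf, sse = sum(stats::resid(fit)^2))
  }
  if (!length(cands)) {
    # fall back to direct bounded minimization of the SSE
    obj <- function(p) sum((v - p[1L] * (exp(p[2L] * tt) - exp(p[3L] * tt)))^2)
    op <- stats::optim(starts[[1L]], obj, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 1000))
    if (op$par[3L] >= op$par[2L])
      stop("fit_second_order: optimizer failed on all starts")
    cands <- list(list(coef = c(a = op$par[[1L]], tau1 = op$par[[2L]],
                                tau2 = op$par[[3L]]),
                       sse = op$value))
  }
  sses <- vapply(cands, `[[`, numeric(1L), "sse")
  best <- which(sses <= min(sses) * (1 + 1e-9))
  if (length(best) > 1L) {
    tau1s <- vapply(cands[best], function(c_) abs(c_$coef[["tau1"]]),
                    numeric(1L))
    best <- best[which.min(tau1s)]
  } else best <- best[1L]
  cf <- cands[[best]]$coef
  new_velocity_model(order = 2L, anchor = NULL,
                     coef = c(a = cf[["a"]], tau1 = cf[["tau1"]],
                              tau2 = cf[["tau2"]]),
                     t = t, tt = tt, v = v)
}

new_velocity_model <- function(order, anchor, coef, t, tt, v) {
  m <- structure(list(order = order, anchor = anchor, coef = coef,
                      t = t, tt = tt, v = v),
                 class = "velocity_model")
  m$fitted <- model_velocity(m, tt)
  m$rms <- rms(v - m$fitted)
  m
}

model_velocity <- function(m, tt) {
  cf <- m$coef
  if (m$order == 1L) cf[["vmax"]] * (1 - exp(-tt / cf[["tau"]]))
  else cf[["a"]] * (exp(cf[["tau1"]] * tt) - exp(cf[["tau2"]] * tt))
}

model_acceleration <- function(m, tt) {
  cf <- m$coef
  if (m$order == 1L) cf[["vmax"]] / cf[["tau"]] * exp(-tt / cf[["tau"]])
  else cf[["a"]] * (cf[["tau1"]] * exp(cf[["tau1"]] * tt) -
                      cf[["tau2"]] * exp(cf[["tau2"]] * tt))
}

#' @export
coef.velocity_model <- function(object, ...) object$coef

#' @export
fitted.velocity_model <- function(object, ...) object$fitted

#' @export
residuals.velocity_model <- function(object, ...) object$v - object$fitted

#' @export
predict.velocity_model <- function(object, t = NULL,
                                   type = c("velocity", "acceleration"),
                                   ...) {
  type <- match.arg(type)
  tt <- if (is.null(t)) object$tt else t - object$t[1L]
  if (type == "velocity") model_velocity(object, tt)
  else model_acceleration(object, tt)
}

#' @export
print.velocity_model <- function(x, ...) {
  if (x$order == 1L) {
    cat(sprintf("First-order velocity model (anchor = %s): vmax = %.4f m/s, tau = %.4f s\n",
                x$anchor, x$coef[["vmax"]], x$coef[["tau"]]))
  } else {
    cat(sprintf("Second-order velocity model: a = %.4f m/s, tau1 = %.6f, tau2 = %.4f 1/s\n",
                x$coef[["a"]], x$coef[["tau1"]], x$coef[["tau2"]]))
  }
  cat(sprintf("  RMS of residuals: %.4f m/s over %d samples\n",
              x$rms, length(x$v)))
  invisible(x)
}

#' @export
summary.velocity_model <- function(object, ...) {
  print(object)
  r <- residuals(object)
  cat(sprintf("  residual range [%.4f, %.4f] m/s\n", min(r), max(r)))
  invisible(object)
}

#' @export
plot.velocity_model <- function(x, ...) {
  graphics::plot(x$tt, x$v, pch = 20, col = "grey60",
                 xlab = "time since sprint start (s)",
                 ylab = "velocity (m/s)",
                 main = sprintf("Order-%d exponential fit", x$order), ...)
  tt <- seq(0, max(x$tt), length.out = 400L)
  graphics::lines(tt, model_velocity(x, tt), lwd = 2)
  invisible(x)
}

#' Mechanical profile: force, power and theoretical parameters
#'
#' Evaluates the fitted velocity model and its analytic derivative on a time
#' grid and derives the horizontal force profile `F(t) = M a_mdl(t)` and
#' power profile `P(t) = F(t) v_mdl(t)` (the dimensionally consistent
#' product; `power = "force_acceleration"` substitutes `F * a`, an
#' alternative definition occasionally seen in print).  Theoretical
#' parameters: `v0` is the velocity at zero model acceleration (for the
#' second-order model the closed-form apex `t* = log(tau1/tau2) /
#' (tau2 - tau1)`; for the first order the anchor velocity), `f0 =
#' a_mdl(0)` in N/kg, and `pmax` the apex of `P/M`, located on the grid and
#' refined by golden-section search around the bracketing samples.
#'
#' @param model A [velocity_model()].
#' @param mass Athlete mass M, kg.
#' @param t_grid Evaluation grid, s (default: 5 ms steps over the data
#'   span).
#' @param power `"force_velocity"` (default) or `"force_acceleration"`.
#' @return An object of class `mechanical_profile`: list with `t`, `v_mdl`,
#'   `a_mdl`, `F_mdl` (N), `P_mdl` (W), `mass`, `v0` (m/s), `f0` (N/kg),
#'   `pmax` (W/kg) and `t_apex` (s, time of zero model acceleration).
#' @export
mechanical_profile <- function(model, mass, t_grid = NULL,
                               power = c("force_velocity",
                                         "force_acceleration")) {
  power <- match.arg(power)
  if (mass <= 0) stop("mechanical_profile: mass must be > 0")
  if (is.null(t_grid)) t_grid <- seq(0, max(model$tt), by = 0.005)
  v_mdl <- model_velocity(model, t_grid)
  a_mdl <- model_acceleration(model, t_grid)
  F_mdl <- mass * a_mdl
  P_mdl <- if (power == "force_velocity") F_mdl * v_mdl else F_mdl * a_mdl
  cf <- model$coef
  if (model$order == 1L) {
    v0 <- cf[["vmax"]]
    f0 <- cf[["vmax"]] / cf[["tau"]]
    t_apex <- Inf
  } else if (cf[["tau1"]] == 0) {
    v0 <- cf[["a"]]  # supremum of the monotone profile
    f0 <- cf[["a"]] * (cf[["tau1"]] - cf[["tau2"]])
    t_apex <- Inf
  } else {
    t_apex <- log(cf[["tau1"]] / cf[["tau2"]]) / (cf[["tau2"]] - cf[["tau1"]])
    v0 <- model_velocity(model, t_apex)
    f0 <- cf[["a"]] * (cf[["tau1"]] - cf[["tau2"]])
  }
  # apex of specific power: grid argmax refined within the bracketing samples
  p_spec <- function(s) {
    vv <- model_velocity(model, s)
    aa <- model_acceleration(model, s)
    if (power == "force_velocity") vv * aa else aa * aa
  }
  i <- which.max(P_mdl)
  lo <- t_grid[max(i - 1L, 1L)]
  hi <- t_grid[min(i + 1L, length(t_grid))]
  pmax <- if (hi > lo)
    stats::optimize(p_spec, c(lo, hi), maximum = TRUE, tol = 1e-10)$objective
  else p_spec(t_grid[i])
  structure(list(t = t_grid, v_mdl = v_mdl, a_mdl = a_mdl, F_mdl = F_mdl,
                 P_mdl = P_mdl, mass = mass, v0 = unname(v0),
                 f0 = unname(f0), pmax = unname(pmax),
                 t_apex = unname(t_apex), model = model, power = power),
            class = "mechanical_profile")
}

#' @export
print.mechanical_profile <- function(x, ...) {
  cat(sprintf("Mechanical sprint profile (M = %g kg, order %d model)\n",
              x$mass, x$model$order))
  cat(sprintf("  v0 = %.3f m/s, f0 = %.3f N/kg, pmax = %.3f W/kg\n",
              x$v0, x$f0, x$pmax))
  invisible(x)
}

#' Force-velocity and power-velocity curves
#'
#' Parametric elimination of time over the accelerating (monotone-velocity)
#' portion of the profile (`t <= t_apex`), in per-unit-mass units.
#'
#' @param profile A [mechanical_profile()].
#' @return A data frame with columns `v` (m/s), `f` (N/kg) and `p` (W/kg).
#' @export
fv_pv_curves <- function(profile) {
  keep <- profile$t <= profile$t_apex
  data.frame(v = profile$v_mdl[keep],
             f = profile$a_mdl[keep],
             p = profile$P_mdl[keep] / profile$mass)
}

#' @export
plot.mechanical_profile <- function(x, ...) {
  cur <- fv_pv_curves(x)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(cur$v, cur$f, type = "l", lwd = 2, xlab = "velocity (m/s)",
                 ylab = "force (N/kg)", main = "F-V profile")
  graphics::plot(cur$v, cur$p, type = "l", lwd = 2, xlab = "velocity (m/s)",
                 ylab = "power (W/kg)", main = "P-V profile")
  invisible(x)
}
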