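#' Decision-tree integral controller configuration
#'
#' The feedback law of the main clamp: if the measured dF/F0 is inside the
#' tolerance band around the target, the wavelength is held; otherwise the
#' wavelength moves by `ki * e` in the direction given by
#' `increment_sign * sign(target - dff)`, where `e = |target - dff|`, and is
#' clipped to the monochromator limits.
#'
#' @param ki Integral gain (nm per percent dF/F0, per frame), >= 0.
#' @param tolerance Tolerance band half-width (percent dF/F0), >= 0. The
#'   check is inclusive: a deviation exactly at the band edge holds.
#' @param lambda_min,lambda_max Wavelength limits (nm).
#' @param increment_sign Polarity of the wavelength increment (+1 if a redder
#'   wavelength raises dF/F0, -1 otherwise).
#' @param start_wavelength Calibration / starting wavelength (nm), within
#'   limits.
#' @return An object of class `ovc_i_controller`.
#' @export
i_controller <- function(ki = 2, tolerance = 1, lambda_min = 400,
                         lambda_max = 600, increment_sign = 1,
                         start_wavelength = 520) {
  stopifnot(ki >= 0, tolerance >= 0, lambda_min < lambda_max,
            increment_sign %in% c(-1, 1),
            start_wavelength >= lambda_min, start_wavelength <= lambda_max)
  structure(list(ki = ki, tolerance = tolerance, lambda_min = lambda_min,
                 lambda_max = lambda_max, increment_sign = increment_sign,
                 start_wavelength = start_wavelength),
            class = "ovc_i_controller")
}

#' PID controller configuration
#'
#' Discrete PID positioned about the calibration wavelength:
#' `u = kp*e + ki*ta*e_sum + kd*(e - e_prev)/ta`, `lambda = lambda0 + u`,
#' with the signed error `e = target - dff`. The integral term is frozen
#' while the wavelength is clipped at a limit (anti-windup).
#'
#' @param kp Proportional gain (nm per percent).
#' @param ki Integral gain (nm per percent per second).
#' @param kd Derivative gain (nm second per percent).
#' @param ta Sampling period (s), > 0.
#' @param lambda0 Calibration wavelength (nm).
#' @param tolerance,lambda_min,lambda_max As for [i_controller()].
#' @return An object of class `ovc_pid_controller`.
#' @export
pid_controller <- function(kp, ki = 0, kd = 0, ta = 0.01, lambda0 = 520,
                           tolerance = 1, lambda_min = 400,
                           lambda_max = 600) {
  stopifnot(ta > 0, lambda_min < lambda_max,
            lambda0 >= lambda_min, lambda0 <= lambda_max)
  structure(list(kp = kp, ki = ki, kd = kd, ta = ta, lambda0 = lambda0,
                 tolerance = tolerance, lambda_min = lambda_min,
                 lambda_max = lambda_max,
                 start_wavelength = lambda0),
            class = "ovc_pid_controller")
}

#' Initial controller state
#'
#' @param config An [i_controller()] or [pid_controller()] configuration.
#' @return An object of class `ovc_controller_state`: `wavelength`, `error`,
#'   `error_sum`, `error_prev`, `status` (one of `"holding"`, `"adapting"`,
#'   `"limit_reached"`).
#' @export
init_controller_state <- function(config) {
  structure(list(wavelength = config$start_wavelength, error = 0,
                 error_sum = 0, error_prev = 0, status = "holding"),
            class = "ovc_controller_state")
}

.clip_lambda <- function(lambda, lo, hi) {
  clipped <- lambda < lo || lambda > hi
  list(lambda = min(max(lambda, lo), hi), clipped = clipped)
}

#' One step of the decision-tree integral controller
#'
#' @param state An [init_controller_state()] object.
#' @param dff Measured (bleach-corrected) dF/F0 (percent).
#' @param target Holding dF/F0 (percent).
#' @param config An [i_controller()] configuration.
#' @return The updated controller state. A non-finite `dff` holds the
#'   previous wavelength and flags the frame (`status = "holding"`,
#'   attribute `flagged`).
#' @export
i_step <- function(state, dff, target, config) {
  if (!is.finite(dff)) {
    state$status <- "holding"
    attr(state, "flagged") <- TRUE
    return(state)
  }
  dev <- target - dff
  if (abs(dev) <= config$tolerance) {
    state$error <- abs(dev)
    state$status <- "holding"
    return(state)
  }
  e <- abs(dev)
  ik <- config$increment_sign * sign(dev)
  cl <- .clip_lambda(state$wavelength + config$ki * e * ik,
                     config$lambda_min, config$lambda_max)
  state$wavelength <- cl$lambda
  state$error <- e
  state$status <- if (cl$clipped) "limit_reached" else "adapting"
  state
}

#' One step of the PID controller
#'
#' Optionally smooths the measurement through a scalar Kalman filter first.
#' Inside the tolerance band the wavelength is held (status `"holding"`),
#' mirroring the decision-tree behavior; the error memory still updates so
#' that integral action resumes consistently.
#'
#' @inheritParams i_step
#' @param config A [pid_controller()] configuration.
#' @param kalman An optional [kalman_state()]; when supplied, the filtered
#'   estimate replaces `dff` and the updated filter is returned alongside.
#' @return The updated controller state; with `kalman`, a list
#'   `list(state, kalman)`.
#' @export
pid_step <- function(state, dff, target, config, kalman = NULL) {
  if (!is.null(kalman)) {
    kalman <- kalman_step(kalman, dff)
    dff <- kalman$x_hat
  }
  if (!is.finite(dff)) {
    state$status <- "holding"
    attr(state, "flagged") <- TRUE
    return(if (is.null(kalman)) state else list(state = state, kalman = kalman))
  }
  e <- target - dff
  hold <- abs(e) <= config$tolerance
  at_limit <- FALSE
  if (!hold) {
    e_sum_try <- state$error_sum + e
    u <- config$kp * e + config$ki * config$ta * e_sum_try +
      config$kd * (e - state$error_prev) / config$ta
    cl <- .clip_lambda(config$lambda0 + u, config$lambda_min,
                       config$lambda_max)
    at_limit <- cl$clipped
    if (!at_limit) state$error_sum <- e_sum_try  # anti-windup freeze
    state$wavelength <- cl$lambda
  }
  state$error <- e
  state$error_prev <- e
  state$status <- if (hold) "holding" else if (at_limit) "limit_reached"
                  else "adapting"
  if (is.null(kalman)) state else list(state = state, kalman = kalman)
}

#' Ziegler-Nichols PID tuning from the critical gain and period
#'
#' Classic closed-loop (ultimate-gain) rules: `kp = 0.6 kp_crit`,
#' `tn = 0.5 t_crit`, `tv = 0.12 t_crit`, then `ki = kp / tn` and
#' `kd = kp * tv`.
#'
#' @param kp_crit Critical proportional gain at sustained oscillation (> 0).
#' @param t_crit Oscillation period (s, > 0).
#' @return An object of class `ovc_zn_tuning` with fields `kp_crit`,
#'   `t_crit`, `kp`, `tn`, `tv`, `ki`, `kd`.
#' @export
zn_tune <- function(kp_crit, t_crit) {
  stopifnot(kp_crit > 0, t_crit > 0)
  kp <- 0.6 * kp_crit
  tn <- 0.5 * t_crit
  tv <- 0.12 * t_crit
  structure(list(kp_crit = kp_crit, t_crit = t_crit, kp = kp, tn = tn,
                 tv = tv, ki = kp / tn, kd = kp * tv),
            class = "ovc_zn_tuning")
}

#' @export
print.ovc_zn_tuning <- function(x, ...) {
  cat(sprintf(
    "Ziegler-Nichols tuning: kp_crit = %.3g, t_crit = %.3g s\n  kp = %.3g, ki = %.3g /s, kd = %.3g s\n",
    x$kp_crit, x$t_crit, x$kp, x$ki, x$kd))
  invisible(x)
}

#' Scalar Kalman filter state
#'
#' One-dimensional Kalman filter with constant system dynamics (system and
#' output matrices fixed at 1), used to smooth the dF/F0 measurement before
#' the PID law.
#'
#' @param x0 Initial estimate (percent dF/F0); conventionally the first
#'   calibration-phase dF/F0.
#' @param p0 Initial estimate variance; defaults to `r`.
#' @param q System-noise covariance (>= 0).
#' @param r Measurement-noise covariance (> 0).
#' @return An object of class `ovc_kalman` with fields `x_hat`, `p`, `q`,
#'   `r`, `a = 1`, `h = 1`, `k_gain`, `s`.
#' @export
kalman_state <- function(x0 = 0, p0 = NULL, q = 1e-3, r = 0.01) {
  stopifnot(r > 0, q >= 0)
  if (is.null(p0)) p0 <- r
  stopifnot(p0 >= 0)
  structure(list(x_hat = x0, p = p0, q = q, r = r, a = 1, h = 1,
                 k_gain = 0, s = NA_real_),
            class = "ovc_kalman")
}

#' One predict-correct cycle of the scalar Kalman filter
#'
#' Prediction `x* = a x_hat`, `p* = a p a + q`; gain `s = h p* h + r`,
#' `k = p* h / s`; correction `x_hat <- x* + k (z - h x*)`,
#' `p <- (1 - k h) p*`.
#'
#' @param state A [kalman_state()] object.
#' @param z New measurement (percent dF/F0).
#' @return The updated `ovc_kalman` state.
#' @export
kalman_step <- function(state, z) {
  x_star <- state$a * state$x_hat
  p_star <- state$a * state$p * state$a + state$q
  s <- state$h * p_star * state$h + state$r
  if (s <= 0) stop("non-positive innovation covariance")
  k <- p_star * state$h / s
  state$x_hat <- x_star + k * (z - state$h * x_star)
  state$p <- (1 - k * state$h) * p_star
  state$k_gain <- k
  state$s <- s
  state
}

#' Find the critical gain and oscillation period of the closed loop
#'
#' Ramps the proportional gain of a P-only controller on a noiseless plant
#' until the closed loop shows sustained (non-decaying) oscillation, then
#' measures the oscillation period from the error zero crossings. The result
#' feeds [zn_tune()].
#'
#' @param plant,sensor Plant and sensor configurations (see
#'   [ovc_plant_config()], [ovc_sensor_config()]).
#' @param target Setpoint used for the probe runs (percent dF/F0).
#' @param lambda0 Calibration wavelength (nm).
#' @param kp_grid Increasing candidate gains (nm per percent).
#' @param frames Probe run length (frames).
#' @param fps Sampling rate (Hz).
#' @return A list with `kp_crit`, `t_crit` (s) and the [zn_tune()] result
#'   `tuning`.
#' @export
find_critical_gain <- function(plant, sensor, target = 3, lambda0 = 520,
                               kp_grid = 2^seq(1, 9, by = 0.5),
                               frames = 300, fps = 100) {
  probe <- function(kp) {
    cfg <- pid_controller(kp = kp, ki = 0, kd = 0, ta = 1 / fps,
                          lambda0 = lambda0, tolerance = 0)
    tr <- .open_probe_run(plant, sensor, cfg, target, frames, fps)
    err <- target - tr$dff
    half <- err[-(1:floor(frames / 2))]
    early <- err[1:floor(frames / 2)]
    list(sustained = stats::sd(half) > 0.45 * stats::sd(early) &&
           stats::sd(half) > 0.05,
         err = err)
  }
  kp_crit <- NA_real_; err <- NULL
  for (kp in kp_grid) {
    pr <- probe(kp)
    if (pr$sustained) { kp_crit <- kp; err <- pr$err; break }
  }
  if (!is.finite(kp_crit))
    stop("no sustained oscillation found over the gain grid")
  sgn <- sign(err[err != 0])
  cross <- which(diff(sgn) != 0)
  if (length(cross) < 3) stop("too few zero crossings to measure the period")
  t_crit <- 2 * mean(diff(cross)) / fps
  list(kp_crit = kp_crit, t_crit = t_crit, tuning = zn_tune(kp_crit, t_crit))
}

# Minimal noiseless closed-loop probe used by find_critical_gain (no
# bleaching, no calibration phase; exact dF/F0 readout).
.open_probe_run <- function(plant, sensor, controller, target, frames, fps) {
  dt <- 1000 / fps
  light <- light_input(controller$start_wavelength, 1, TRUE)
  st <- init_plant_state(plant, light)
  cs <- init_controller_state(controller)
  dff <- numeric(frames)
  pl <- plant; pl$noise_sd <- 0
  for (k in seq_len(frames)) {
    light$wavelength <- cs$wavelength
    st <- step_plant(st, light, pl, dt = dt)
    dff[k] <- sensor$dff_per_mv * (st$v_mean - sensor$reference_voltage)
    cs <- pid_step(cs, dff[k], target, controller)
  }
  list(dff = dff)
}
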