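#' Protocol specification for a closed-loop run
#'
#' @param targets Holding dF/F0 values (percent), one per step (three- or
#'   four-step protocols are typical, e.g. `c(0, -5, 5, 0)`).
#' @param frames_per_step Frames per step (recycled to the number of steps).
#' @param calibration_frames Frames of the initial bleach-calibration phase
#'   (default 20 s at 100 Hz).
#' @param fps Sampling / control rate (Hz); one controller update per frame.
#' @param intensity Monochromator intensity in \[0, 1\].
#' @param f0_window Leading corrected frames averaged into the baseline F0.
#' @param seed Optional RNG seed; a seeded run is fully reproducible.
#' @return An object of class `ovc_protocol`.
#' @export
ovc_protocol <- function(targets = c(0, -5, 5, 0), frames_per_step = 200,
                         calibration_frames = 2000, fps = 100, intensity = 1,
                         f0_window = 50, seed = NULL) {
  stopifnot(all(frames_per_step > 0), calibration_frames >= 10, fps > 0)
  structure(list(targets = targets,
                 frames_per_step = rep_len(as.integer(frames_per_step),
                                           length(targets)),
                 calibration_frames = as.integer(calibration_frames),
                 fps = fps, intensity = intensity,
                 f0_window = as.integer(f0_window), seed = seed),
            class = "ovc_protocol")
}

# Shared closed-/open-loop engine. `lambda_fun(k, cs)` returns the wavelength
# and intensity for clamp frame k (1-based); `update_fun(cs, dff, k)` returns
# the updated controller state (NULL update = open loop).
.run_engine <- function(protocol, plant, sensor, controller, kalman = NULL,
                        seed = protocol$seed, target_by_frame,
                        open_loop_wave = NULL, cal_mono_on = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / protocol$fps
  sensor$frame_period <- dt
  ncal <- protocol$calibration_frames
  nclamp <- length(target_by_frame)
  lam0 <- controller$start_wavelength
  cal_int <- if (cal_mono_on) protocol$intensity else 0
  cal_light <- light_input(lam0, cal_int, TRUE,
                           c(controller$lambda_min, controller$lambda_max))
  ev <- plant$event_generator
  if (!is.null(ev) && identical(ev$align, "clamp"))
    plant$event_generator$start_ms <- ev$start_ms + ncal * dt
  st <- init_plant_state(plant, cal_light)

  n <- ncal + nclamp
  gray_raw <- numeric(n); volt <- numeric(n)
  wl <- numeric(n); status <- character(n)

  for (k in seq_len(ncal)) {
    st <- step_plant(st, cal_light, plant, dt = dt)
    gray_raw[k] <- sample_frame(st$v_mean, k - 1L, sensor)$gray
    volt[k] <- st$v_mean
    wl[k] <- if (cal_int > 0) lam0 else NA_real_
    status[k] <- "C"
  }

  fit <- fit_bleach(gray_raw[seq_len(ncal)])
  if (!fit$converged)
    warning("bleach fit did not converge; falling back to a flat profile")
  offs_end <- fit$a * exp(-fit$b * (n - 1)) + fit$c
  if (!is.finite(offs_end) || offs_end <= 0)
    stop("degenerate bleach fit: non-positive predicted offset over the run")
  gray_corr <- correct_frame(gray_raw[seq_len(ncal)], seq_len(ncal) - 1L, fit)
  baseline <- make_baseline(gray_corr, protocol$f0_window)
  dff <- compute_dff(gray_corr, baseline)

  cs <- init_controller_state(controller)
  if (!is.null(kalman)) kalman$x_hat <- dff[1]

  gray_corr <- c(gray_corr, numeric(nclamp))
  dff <- c(dff, numeric(nclamp))
  for (k in seq_len(nclamp)) {
    i <- ncal + k
    if (is.null(open_loop_wave)) {
      li <- light_input(cs$wavelength, protocol$intensity, TRUE,
                        c(controller$lambda_min, controller$lambda_max))
    } else {
      w <- open_loop_wave((k - 1) * dt)
      li <- light_input(w$wavelength, w$intensity, TRUE,
                        c(controller$lambda_min, controller$lambda_max))
    }
    st <- step_plant(st, li, plant, dt = dt)
    gray_raw[i] <- sample_frame(st$v_mean, i - 1L, sensor)$gray
    volt[i] <- st$v_mean
    gray_corr[i] <- correct_frame(gray_raw[i], i - 1L, fit)
    dff[i] <- compute_dff(gray_corr[i], baseline)
    wl[i] <- li$wavelength
    if (is.null(open_loop_wave)) {
      upd <- if (is.null(kalman))
        i_or_pid_step(cs, dff[i], target_by_frame[k], controller)
      else
        pid_step(cs, dff[i], target_by_frame[k], controller, kalman)
      if (is.list(upd) && !is.null(upd$kalman)) {
        cs <- upd$state; kalman <- upd$kalman
      } else cs <- upd
      status[i] <- c(holding = "H", adapting = "A",
                     limit_reached = "L")[[cs$status]]
    } else {
      status[i] <- "H"
    }
  }

  frames <- data.frame(
    frame = seq_len(n) - 1L,
    time_ms = (seq_len(n) - 1L) * dt,
    gray_raw = gray_raw,
    gray_corr = gray_corr,
    dff_pct = dff,
    wavelength_nm = wl,
    status = status,
    target_pct = c(rep(NA_real_, ncal), target_by_frame),
    voltage_mv = volt)
  structure(list(frames = frames, bleach_fit = fit, baseline = baseline,
                 protocol = protocol, controller = controller,
                 plant = plant, sensor = sensor, seed = seed),
            class = "ovc_session")
}

# Dispatch one controller update by configuration class.
i_or_pid_step <- function(cs, dff, target, controller) {
  if (inherits(controller, "ovc_pid_controller"))
    pid_step(cs, dff, target, controller)
  else
    i_step(cs, dff, target, controller)
}

#' Run a closed-loop clamp session
#'
#' Calibration phase (imaging laser plus start wavelength) for the bleach
#' fit and baseline F0, then the step protocol under feedback: each frame the
#' bleach-corrected dF/F0 is compared with the step's holding value and the
#' controller shifts the monochromator wavelength, which takes effect on the
#' next frame. Fully reproducible for a given seed.
#'
#' @param protocol An [ovc_protocol()] object.
#' @param plant An [ovc_plant_config()] object.
#' @param sensor An [ovc_sensor_config()] object.
#' @param controller An [i_controller()] or [pid_controller()] configuration.
#' @param kalman Optional [kalman_state()] used to smooth the measurement
#'   (PID controller only).
#' @param seed RNG seed (defaults to the protocol's).
#' @return An `ovc_session` object: `$frames` is the per-frame table
#'   (frame, time_ms, gray_raw, gray_corr, dff_pct, wavelength_nm, status,
#'   target_pct, voltage_mv), plus the bleach fit, baseline and the
#'   configurations. Status codes: `C` calibration, `H` holding, `A`
#'   adapting, `L` wavelength limit reached.
#' @export
run_session <- function(protocol, plant, sensor, controller, kalman = NULL,
                        seed = protocol$seed) {
  target_by_frame <- rep(protocol$targets, protocol$frames_per_step)
  .run_engine(protocol, plant, sensor, controller, kalman, seed,
              target_by_frame)
}

#' Run a session with live (scheduled) target changes
#'
#' Emulates on-the-run target selection: the holding value changes at the
#' scheduled times (applied at frame boundaries), with the controller running
#' continuously. A single schedule entry is equivalent to a one-step
#' [run_session()].
#'
#' @param schedule A data frame with columns `time_ms` (non-decreasing,
#'   relative to clamp-phase start) and `target` (percent dF/F0).
#' @param total_frames Clamp-phase length (frames).
#' @inheritParams run_session
#' @return An `ovc_session` object.
#' @export
on_the_run <- function(schedule, total_frames, protocol, plant, sensor,
                       controller, kalman = NULL, seed = protocol$seed) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1,
            !is.unsorted(schedule$time_ms))
  dt <- 1000 / protocol$fps
  tms <- (seq_len(total_frames) - 1L) * dt
  idx <- findInterval(tms, schedule$time_ms)
  idx[idx < 1L] <- 1L
  target_by_frame <- schedule$target[idx]
  .run_engine(protocol, plant, sensor, controller, kalman, seed,
              target_by_frame)
}

#' Run the 11-step pseudo-I/V protocol
#'
#' Clamps dF/F0 at 11 equally spaced targets between the lower and upper
#' limits (inclusive) and summarizes each step by the mean achieved dF/F0 and
#' mean wavelength over the last 25 percent of its frames. In inverse mode
#' the wavelengths of a forward result are played back open-loop and the
#' resulting dF/F0 recorded.
#'
#' @param limits Length-2 numeric: lower and upper dF/F0 limits (percent).
#' @inheritParams run_session
#' @param frames_per_step Frames per step.
#' @param inverse_of A forward `ovc_pseudo_iv` result; when supplied, its
#'   per-step mean wavelengths are presented open-loop instead of closed-loop
#'   targets.
#' @return An object of class `ovc_pseudo_iv`: a data frame with one row per
#'   step (`target`, `dff_achieved`, `wavelength`) and the full session as
#'   attribute `"session"`.
#' @export
run_pseudo_iv <- function(limits = c(-5, 5), protocol, plant, sensor,
                          controller, frames_per_step = 100,
                          seed = protocol$seed, inverse_of = NULL) {
  stopifnot(limits[1] < limits[2])
  targets <- seq(limits[1], limits[2], length.out = 11)
  protocol$targets <- targets
  protocol$frames_per_step <- rep_len(as.integer(frames_per_step), 11L)
  if (is.null(inverse_of)) {
    ses <- run_session(protocol, plant, sensor, controller, seed = seed)
  } else {
    stopifnot(nrow(inverse_of) == 11)
    wl_steps <- inverse_of$wavelength
    dt <- 1000 / protocol$fps
    step_ms <- frames_per_step * dt
    wave <- function(t) {
      i <- min(11L, 1L + as.integer(t %/% step_ms))
      list(wavelength = wl_steps[i], intensity = protocol$intensity)
    }
    ses <- .run_engine(protocol, plant, sensor, controller, seed = seed,
                       target_by_frame = rep(targets, protocol$frames_per_step),
                       open_loop_wave = wave)
  }
  f <- ses$frames[ses$frames$status != "C", ]
  step_id <- rep(seq_len(11L), protocol$frames_per_step)
  out <- do.call(rbind, lapply(seq_len(11L), function(i) {
    g <- f[step_id == i, ]
    w <- max(1L, floor(nrow(g) * 0.25))
    tail_g <- g[(nrow(g) - w + 1L):nrow(g), ]
    data.frame(target = targets[i],
               dff_achieved = mean(tail_g$dff_pct),
               wavelength = mean(tail_g$wavelength_nm))
  }))
  structure(out, class = c("ovc_pseudo_iv", "data.frame"), session = ses)
}

#' Open-loop optical current clamp
#'
#' Plays a wavelength waveform (single pulse, step ramp or continuous ramp)
#' while recording the bleach-corrected dF/F0, mirroring an optical
#' current-clamp experiment. The calibration phase runs with the imaging
#' laser only (monochromator off).
#'
#' @param waveform A waveform from [cc_pulse()], [cc_ramp()] or a function
#'   `f(t_ms)` returning `list(wavelength, intensity)`.
#' @param clamp_frames Playback length (frames).
#' @inheritParams run_session
#' @return An `ovc_session` object (all clamp frames have status `H`).
#' @export
run_current_clamp <- function(waveform, clamp_frames, protocol, plant,
                              sensor, controller = i_controller(),
                              seed = protocol$seed) {
  .run_engine(protocol, plant, sensor, controller, seed = seed,
              target_by_frame = rep(NA_real_, clamp_frames),
              open_loop_wave = waveform, cal_mono_on = FALSE)
}

#' Current-clamp waveforms
#'
#' `cc_pulse` presents a single pulse of fixed wavelength and duration;
#' `cc_ramp` a linear wavelength ramp, optionally quantized into steps.
#' Outside the pulse/ramp the monochromator is off.
#'
#' @param wavelength Pulse wavelength (nm).
#' @param start_ms,duration_ms Pulse/ramp timing (ms, clamp-phase relative).
#' @param intensity Monochromator intensity in \[0, 1\].
#' @return A waveform function for [run_current_clamp()].
#' @export
cc_pulse <- function(wavelength, start_ms, duration_ms, intensity = 1) {
  force(wavelength); force(start_ms); force(duration_ms); force(intensity)
  function(t) {
    on <- t >= start_ms && t < start_ms + duration_ms
    list(wavelength = wavelength, intensity = if (on) intensity else 0)
  }
}

#' @rdname cc_pulse
#' @param from,to Ramp endpoints (nm).
#' @param n_steps Number of discrete steps (`Inf` for a continuous ramp).
#' @export
cc_ramp <- function(from, to, start_ms, duration_ms, intensity = 1,
                    n_steps = Inf) {
  force(from); force(to)
  function(t) {
    if (t < start_ms || t >= start_ms + duration_ms)
      return(list(wavelength = from, intensity = 0))
    frac <- (t - start_ms) / duration_ms
    if (is.finite(n_steps)) frac <- floor(frac * n_steps) / (n_steps - 1)
    list(wavelength = from + (to - from) * min(1, frac),
         intensity = intensity)
  }
}

#' Write / read a session results file
#'
#' UTF-8 text: `# key: value` header lines (protocol parameters, bleach-fit
#' a, b, c and R-squared, frame rate), then a tab-separated table with columns
#' `frame`, `time_ms`, `gray_raw`, `gray_corr`, `dff_pct`, `wavelength_nm`,
#' `status`. Numeric formatting is fixed, so identical sessions produce
#' byte-identical files.
#'
#' @param session An `ovc_session` object.
#' @param path Output file path.
#' @return `write_session` returns `path` invisibly; `read_session` returns a
#'   list with `header` (named character) and `frames` (data frame).
#' @export
write_session <- function(session, path) {
  p <- session$protocol; b <- session$bleach_fit
  hdr <- c(
    targets = paste(p$targets, collapse = ","),
    frames_per_step = paste(p$frames_per_step, collapse = ","),
    calibration_frames = p$calibration_frames,
    fps = p$fps,
    intensity = p$intensity,
    tolerance = session$controller$tolerance,
    lambda_min = session$controller$lambda_min,
    lambda_max = session$controller$lambda_max,
    start_wavelength = session$controller$start_wavelength,
    seed = if (is.null(session$seed)) "NA" else session$seed,
    bleach_a = sprintf("%.6f", b$a),
    bleach_b = sprintf("%.8f", b$b),
    bleach_c = sprintf("%.6f", b$c),
    bleach_r_squared = sprintf("%.6f", b$r_squared),
    f0 = sprintf("%.6f", session$baseline$f0))
  f <- session$frames
  lines <- c(
    paste0("# ", names(hdr), ": ", unname(hdr)),
    paste("frame", "time_ms", "gray_raw", "gray_corr", "dff_pct",
          "wavelength_nm", "status", sep = "\t"),
    sprintf("%d\t%.3f\t%.0f\t%.4f\t%.5f\t%.2f\t%s",
            f$frame, f$time_ms, f$gray_raw, f$gray_corr, f$dff_pct,
            f$wavelength_nm, f$status))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  hl <- grep("^# ", lines)
  header <- stats::setNames(sub("^# [^:]+: ", "", lines[hl]),
                            sub("^# ([^:]+):.*$", "\\1", lines[hl]))
  frames <- utils::read.delim(text = lines[-hl], header = TRUE,
                              stringsAsFactors = FALSE)
  list(header = header, frames = frames)
}

#' @export
print.ovc_session <- function(x, ...) {
  f <- x$frames
  ncal <- sum(f$status == "C")
  cat(sprintf("OVC session: %d calibration + %d clamp frames at %g Hz\n",
              ncal, nrow(f) - ncal, x$protocol$fps))
  print(x$bleach_fit)
  cl <- f[f$status != "C", ]
  if (nrow(cl) && any(!is.na(cl$target_pct))) {
    dev <- abs(cl$dff_pct - cl$target_pct)
    cat(sprintf("  clamp-phase |dev|: median %.3f%%, within tolerance %.1f%% of frames\n",
                stats::median(dev, na.rm = TRUE),
                100 * mean(dev <= x$controller$tolerance, na.rm = TRUE)))
  }
  st <- table(cl$status)
  cat("  status counts:", paste(names(st), st, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.ovc_session <- function(object, ...) {
  q <- control_quality(object)
  print(object)
  cat(sprintf("  saturation fraction: %.3f\n", q$saturation_fraction))
  invisible(q)
}

#' @export
plot.ovc_session <- function(x, ...) {
  f <- x$frames
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(f$time_ms / 1000, f$dff_pct, type = "l", xlab = "time (s)",
                 ylab = "dF/F0 (%)", ...)
  cl <- !is.na(f$target_pct)
  if (any(cl))
    graphics::lines(f$time_ms[cl] / 1000, f$target_pct[cl], col = "red",
                    lty = 2)
  graphics::plot(f$time_ms / 1000, f$wavelength_nm, type = "l",
                 xlab = "time (s)", ylab = "wavelength (nm)")
  invisible(x)
}

#' Static closed-loop maps of a plant/sensor pair
#'
#' `static_dff(lambda)` is the steady-state dF/F0 under the imaging laser
#' plus monochromator light at `lambda`; `wavelength_for_dff(target)` inverts
#' it by bisection (the analytic fixed point a converged integral controller
#' must reach). Both ignore noise and events.
#'
#' @param plant,sensor Plant and sensor configurations.
#' @param lambda Wavelength (nm), vectorized.
#' @param intensity Monochromator intensity.
#' @return `static_dff`: percent dF/F0. `wavelength_for_dff`: nm.
#' @export
static_dff <- function(lambda, plant, sensor, intensity = 1) {
  vapply(lambda, function(l) {
    v <- plant_steady_voltage(plant, light_input(l, intensity, TRUE))
    sensor$dff_per_mv * (v - sensor$reference_voltage)
  }, 0)
}

#' @rdname static_dff
#' @param target dF/F0 target (percent).
#' @param lambda_range Search interval (nm).
#' @export
wavelength_for_dff <- function(target, plant, sensor, intensity = 1,
                               lambda_range = c(400, 600)) {
  f <- function(l) static_dff(l, plant, sensor, intensity) - target
  stats::uniroot(f, lambda_range, tol = 1e-4)$root
}
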