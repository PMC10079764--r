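#' Photocurrent channel parameters
#'
#' Describes one light-gated conductance of the simulated cell: a Gaussian
#' action spectrum, a peak current at the reference driving force, a reversal
#' potential and first-order activation kinetics. `laser_crosstalk` is the
#' fractional activation caused by the far-red imaging laser (the red-shifted
#' depolarizer absorbs some 637 nm light; a blue-shifted hyperpolarizer does
#' not).
#'
#' @param peak_wavelength Peak of the action spectrum (nm).
#' @param spectral_width Gaussian sigma of the action spectrum (nm), > 0.
#' @param max_current Current at full activation, full spectral drive and the
#'   reference driving force (pA). Positive for a depolarizing channel,
#'   negative for a hyperpolarizing one (depolarizing current is positive
#'   throughout the package).
#' @param reversal_potential Reversal potential (mV).
#' @param activation_tau First-order activation time constant (ms), > 0.
#' @param laser_crosstalk Fractional activation by the imaging laser, in
#'   \[0, 1\].
#' @return An object of class `ovc_channel`.
#' @export
ovc_channel <- function(peak_wavelength, spectral_width, max_current,
                        reversal_potential, activation_tau,
                        laser_crosstalk = 0) {
  stopifnot(is.numeric(peak_wavelength), length(peak_wavelength) == 1L,
            spectral_width > 0, activation_tau > 0,
            laser_crosstalk >= 0, laser_crosstalk <= 1)
  structure(list(peak_wavelength = peak_wavelength,
                 spectral_width = spectral_width,
                 max_current = max_current,
                 reversal_potential = reversal_potential,
                 activation_tau = activation_tau,
                 laser_crosstalk = laser_crosstalk),
            class = "ovc_channel")
}

#' Intrinsic event generator specification
#'
#' Stereotyped action potentials injected as current waveforms: an
#' exponential rise with time constant `ap_rise_tau` toward a plateau, held
#' until `ap_fwhm` after onset, then an exponential repolarization with the
#' same time constant; the full width at half maximum of the resulting pulse
#' equals `ap_fwhm`. The injected current is `leak_conductance *
#' ap_amplitude * shape`: `ap_amplitude` is the quasi-static deflection the
#' pulse would produce across the leak alone, so open photoconductances
#' shunt the observed deflection below it (the tissue presets calibrate
#' `ap_amplitude` against the observed fluorescence amplitudes).
#' `periodic_ap` fires at a fixed rate (Hz); `interval_ap` fires at a fixed
#' inter-event interval (s).
#'
#' @param kind One of `"periodic_ap"`, `"interval_ap"`, `"none"`.
#' @param rate_or_interval Firing rate (Hz) for `periodic_ap`, inter-event
#'   interval (s) for `interval_ap`.
#' @param ap_amplitude Peak voltage deflection (mV), > 0.
#' @param ap_fwhm Full width at half maximum of the deflection (ms), > 0;
#'   must exceed `2 * ap_rise_tau` so the plateau is reached.
#' @param ap_rise_tau Rise (and repolarization) time constant (ms), > 0.
#' @param start_ms Onset of the first event (ms); defaults to a quarter
#'   period.
#' @param align `"session"` counts event times from the start of the
#'   recording; `"clamp"` from the start of the clamp phase (the session
#'   engine shifts the schedule by the calibration length), emulating
#'   activity that begins after the calibration — a clean calibration is the
#'   experimenter's choice of acquisition timing.
#' @return An object of class `ovc_events` (or `NULL` for `kind = "none"`).
#' @export
ovc_events <- function(kind = c("periodic_ap", "interval_ap", "none"),
                       rate_or_interval = 4, ap_amplitude = 50,
                       ap_fwhm = 150, ap_rise_tau = 15, start_ms = NULL,
                       align = c("session", "clamp")) {
  kind <- match.arg(kind)
  if (kind == "none") return(NULL)
  stopifnot(rate_or_interval > 0, ap_amplitude > 0, ap_rise_tau > 0,
            ap_fwhm > 2 * ap_rise_tau)
  period <- if (kind == "periodic_ap") 1000 / rate_or_interval
            else 1000 * rate_or_interval
  if (is.null(start_ms)) start_ms <- period / 4
  structure(list(kind = kind, rate_or_interval = rate_or_interval,
                 ap_amplitude = ap_amplitude, ap_fwhm = ap_fwhm,
                 ap_rise_tau = ap_rise_tau, start_ms = start_ms,
                 align = match.arg(align)),
            class = "ovc_events")
}

# Normalized plateau pulse (peak ~1), vectorized over t (ms >= 0). The rise
# half-crossing sits at tau*log(2) and the fall half-crossing at
# fwhm + tau*log(2), so the FWHM equals ap_fwhm.
.event_shape <- function(t, ev) {
  tau <- ev$ap_rise_tau
  t_off <- ev$ap_fwhm
  s <- ifelse(t < t_off,
              1 - exp(-t / tau),
              (1 - exp(-t_off / tau)) * exp(-(t - t_off) / tau))
  pmax(s, 0)
}

#' Plant configuration: the simulated excitable cell
#'
#' Single-compartment membrane with a leak conductance, two spectrally opposed
#' photocurrents, an optional depolarization-activated inward current (a
#' voltage-gated Ca2+ channel stand-in), optional intrinsic action potentials
#' and Ornstein-Uhlenbeck membrane noise emulating slow synaptic background.
#'
#' @param capacitance Membrane capacitance (pF), > 0.
#' @param leak_conductance Leak conductance (nS), > 0.
#' @param leak_reversal Leak reversal potential (mV).
#' @param resting_potential Resting potential (mV); also the reference voltage
#'   for the normalized photocurrent driving force.
#' @param depolarizer,hyperpolarizer [ovc_channel()] objects.
#' @param noise_sd Stationary standard deviation of the membrane-noise process
#'   (mV); 0 disables noise.
#' @param noise_tau Correlation time of the membrane-noise process (ms).
#' @param event_generator An [ovc_events()] object or `NULL`.
#' @param event_gate Optional regenerative trigger for the events:
#'   `list(vhalf, floor, trigger_ms, pacemaker_tau)`. Each scheduled event
#'   then starts as a sub-threshold pacemaker drive (`floor` times the event
#'   current, rising slowly with `pacemaker_tau`, default the event rise
#'   tau). Only if the membrane voltage crosses `vhalf` within `trigger_ms`
#'   of onset does the full stereotyped waveform fire (from the trigger
#'   time); otherwise the attempt fails and the drive is withdrawn.
#'   Feedback that holds the voltage below `vhalf` therefore aborts the
#'   spike, which is how dynamic clamping suppresses activity in
#'   spontaneously active cells. `NULL` injects every waveform
#'   unconditionally.
#' @param vgcc Optional depolarization-activated current:
#'   `list(gmax, vhalf, slope, reversal)` with `gmax` in pA at the reference
#'   driving force, Boltzmann activation `1/(1+exp(-(V-vhalf)/slope))`.
#' @return An object of class `ovc_plant`.
#' @export
ovc_plant_config <- function(capacitance, leak_conductance, leak_reversal,
                             resting_potential, depolarizer, hyperpolarizer,
                             noise_sd = 0, noise_tau = 250,
                             event_generator = NULL, event_gate = NULL,
                             vgcc = NULL) {
  stopifnot(capacitance > 0, leak_conductance > 0, noise_sd >= 0,
            noise_tau > 0, inherits(depolarizer, "ovc_channel"),
            inherits(hyperpolarizer, "ovc_channel"))
  if (!is.null(event_generator)) stopifnot(inherits(event_generator, "ovc_events"))
  structure(list(capacitance = capacitance,
                 leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal,
                 resting_potential = resting_potential,
                 depolarizer = depolarizer, hyperpolarizer = hyperpolarizer,
                 noise_sd = noise_sd, noise_tau = noise_tau,
                 event_generator = event_generator, event_gate = event_gate,
                 vgcc = vgcc),
            class = "ovc_plant")
}

#' Monochromator / laser light input
#'
#' @param wavelength Monochromator wavelength (nm).
#' @param intensity Monochromator intensity in \[0, 1\]; 0 means
#'   monochromator off.
#' @param laser_on Is the far-red imaging laser on?
#' @param lambda_range Allowed monochromator range (nm) when it is on.
#' @return An object of class `ovc_light`.
#' @export
light_input <- function(wavelength = 520, intensity = 1, laser_on = TRUE,
                        lambda_range = c(400, 600)) {
  stopifnot(intensity >= 0, intensity <= 1)
  if (intensity > 0 &&
      (wavelength < lambda_range[1] || wavelength > lambda_range[2]))
    stop("wavelength outside the configured monochromator range")
  structure(list(wavelength = wavelength, intensity = intensity,
                 laser_on = isTRUE(laser_on)),
            class = "ovc_light")
}

#' Initial plant state
#'
#' Starts at the resting potential with both photo-gates relaxed to the
#' steady-state drive of `light` (dark by default).
#'
#' @param config An [ovc_plant_config()] object.
#' @param light An [ovc_light] object, or `NULL` for darkness.
#' @return An object of class `ovc_state` with fields `voltage` (mV),
#'   `act_dep`, `act_hyp` (gating, in \[0,1\]), `time` (ms) and `noise`
#'   (mV, hidden noise-process state).
#' @export
init_plant_state <- function(config, light = NULL) {
  dd <- if (is.null(light)) 0 else spectral_drive(light, config$depolarizer)
  dh <- if (is.null(light)) 0 else spectral_drive(light, config$hyperpolarizer)
  structure(list(voltage = config$resting_potential,
                 act_dep = dd, act_hyp = dh, time = 0, noise = 0,
                 events = NULL),
            class = "ovc_state")
}

#' Gaussian action spectrum
#'
#' Relative spectral sensitivity `exp(-(lambda - peak)^2 / (2 width^2))`,
#' equal to 1 at the peak.
#'
#' @param wavelength Wavelength(s) in nm.
#' @param channel An [ovc_channel()] object.
#' @return Sensitivity in (0, 1\], vectorized over `wavelength`.
#' @export
spectral_sensitivity <- function(wavelength, channel) {
  exp(-(wavelength - channel$peak_wavelength)^2 /
        (2 * channel$spectral_width^2))
}

#' Total spectral drive of a channel under a light input
#'
#' Monochromator drive (action spectrum times intensity) plus laser crosstalk,
#' clipped to \[0, 1\]. This is both the steady-state gating target and the
#' instantaneous photon-flux factor of the photocurrent.
#'
#' @inheritParams spectral_sensitivity
#' @param light An [ovc_light] object.
#' @return Drive in \[0, 1\].
#' @export
spectral_drive <- function(light, channel) {
  d <- 0
  if (light$intensity > 0)
    d <- spectral_sensitivity(light$wavelength, channel) * light$intensity
  if (light$laser_on) d <- d + channel$laser_crosstalk
  min(max(d, 0), 1)
}

# Driving force normalized to 1 at the reference (resting) potential.
.df_norm <- function(v, e_rev, v_ref) (v - e_rev) / (v_ref - e_rev)

#' Instantaneous photocurrent
#'
#' Sum over the two channels of
#' `max_current * activation * (V - E_rev) / (V_ref - E_rev)`, with
#' depolarizing current positive. The spectrum enters through the gate:
#' activation relaxes toward [spectral_drive()] with the channel's time
#' constant (see [step_plant()]), so at steady state the current is
#' proportional to the spectral drive. The optional voltage-gated inward
#' current is not included (it is intrinsic, not light-gated). `light` is
#' accepted for interface symmetry but the current depends on it only through
#' the gating state.
#'
#' @param state An [ovc_state] object.
#' @param light An [ovc_light] object (unused at fixed gating).
#' @param config An [ovc_plant_config()] object.
#' @return Photocurrent in pA.
#' @export
photocurrent <- function(state, light, config) {
  v <- state$voltage; vr <- config$resting_potential
  dep <- config$depolarizer; hyp <- config$hyperpolarizer
  dep$max_current * state$act_dep *
    .df_norm(v, dep$reversal_potential, vr) +
    hyp$max_current * state$act_hyp *
    .df_norm(v, hyp$reversal_potential, vr)
}

# Intrinsic voltage-gated current (pA), depolarizing positive.
.vgcc_current <- function(v, vgcc, v_ref) {
  if (is.null(vgcc)) return(0)
  m <- 1 / (1 + exp(-(v - vgcc$vhalf) / vgcc$slope))
  vgcc$gmax * m * .df_norm(v, vgcc$reversal, v_ref)
}

# Event current onsets (ms) intersecting [t0, t1); deterministic schedules.
.event_onsets <- function(ev, t0, t1) {
  if (is.null(ev)) return(numeric(0))
  period <- if (ev$kind == "periodic_ap") 1000 / ev$rate_or_interval
            else 1000 * ev$rate_or_interval
  first <- ev$start_ms
  tail_ms <- ev$ap_fwhm + 8 * ev$ap_rise_tau
  k0 <- max(0, floor((t0 - tail_ms - first) / period))
  k1 <- ceiling((t1 - first) / period)
  on <- first + period * (k0:max(k1, k0))
  on[on < t1 & on + tail_ms > t0]
}

#' Advance the plant by one frame period
#'
#' Explicit-Euler integration with a fixed inner substep (default 0.1 ms).
#' Gating relaxes exactly (closed form) toward the spectral drive; the membrane
#' equation `C dV/dt = -g_leak (V - E_leak) + I_photo + I_vgcc + I_event +
#' I_inject + g_leak * n` is stepped per substep, with `n` the
#' Ornstein-Uhlenbeck noise state. With `noise_sd = 0` the update is
#' deterministic. Uses R's global RNG stream.
#'
#' @param state An [ovc_state] object.
#' @param light An [ovc_light] object, held fixed over the step.
#' @param config An [ovc_plant_config()] object.
#' @param i_inject Injected current (pA), constant over the step.
#' @param dt Step duration (ms), > 0.
#' @param dt_inner Inner integration substep (ms).
#' @return The updated `ovc_state`; the extra field `v_mean` holds the mean
#'   voltage over the step (what a camera exposure integrates).
#' @export
step_plant <- function(state, light, config, i_inject = 0, dt,
                       dt_inner = 0.1) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$voltage, state$act_dep, state$act_hyp))))
    stop("non-finite plant state")
  n_sub <- max(1L, as.integer(round(dt / dt_inner)))
  h <- dt / n_sub
  dep <- config$depolarizer; hyp <- config$hyperpolarizer
  vr <- config$resting_potential
  dd <- spectral_drive(light, dep)
  dh <- spectral_drive(light, hyp)

  # closed-form gate trajectories at substep ends
  kd <- exp(-h * (1:n_sub) / dep$activation_tau)
  kh <- exp(-h * (1:n_sub) / hyp$activation_tau)
  ad <- dd + (state$act_dep - dd) * kd
  ah <- dh + (state$act_hyp - dh) * kh

  # photocurrent is affine in V at fixed gating: I = alpha + beta * V
  cd <- dep$max_current * ad / (vr - dep$reversal_potential)
  ch <- hyp$max_current * ah / (vr - hyp$reversal_potential)
  alpha <- -cd * dep$reversal_potential - ch * hyp$reversal_potential
  beta <- cd + ch

  tt <- state$time + h * (1:n_sub)
  ev <- config$event_generator
  gate <- config$event_gate
  events <- state$events
  gl <- config$leak_conductance
  if (!is.null(ev)) {
    on <- .event_onsets(ev, state$time, state$time + dt)
    on <- setdiff(on, if (is.null(events)) numeric(0) else events$onset)
    if (length(on))
      events <- rbind(events,
                      data.frame(onset = on,
                                 status = if (is.null(gate)) "triggered"
                                          else "pending",
                                 fail_rel = NA_real_,
                                 trig_rel = if (is.null(gate)) 0
                                            else NA_real_))
    tail_ms <- ev$ap_fwhm + 8 * ev$ap_rise_tau
    if (!is.null(events) && nrow(events)) {
      rel_now <- state$time - events$onset
      done <- (events$status == "triggered" &
                 rel_now - events$trig_rel > tail_ms) |
              (events$status == "failed" &
                 rel_now - events$fail_rel > tail_ms)
      events <- events[!done, , drop = FALSE]
    }
  }
  have_events <- !is.null(events) && nrow(events) > 0

  el <- config$leak_reversal
  cap <- config$capacitance
  v <- state$voltage; nz <- state$noise
  use_noise <- config$noise_sd > 0
  if (use_noise) {
    z <- stats::rnorm(n_sub)
    a_n <- h / config$noise_tau
    s_n <- config$noise_sd * sqrt(2 * a_n)
  }
  vgcc <- config$vgcc
  vtrace <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    if (use_noise) nz <- nz - a_n * nz + s_n * z[i]
    ie <- 0
    if (have_events) {
      for (j in seq_len(nrow(events))) {
        rel <- tt[i] - events$onset[j]
        if (rel <= 0) next
        stj <- events$status[j]
        if (stj == "pending") {
          pm_tau <- if (is.null(gate$pacemaker_tau)) ev$ap_rise_tau
                    else gate$pacemaker_tau
          if (v >= gate$vhalf) {
            events$status[j] <- stj <- "triggered"
            events$trig_rel[j] <- rel
          } else if (rel > gate$trigger_ms) {
            events$status[j] <- stj <- "failed"
            events$fail_rel[j] <- rel
          } else {
            ie <- ie + gl * ev$ap_amplitude * gate$floor *
              (1 - exp(-rel / pm_tau))
          }
        }
        if (stj == "triggered") {
          ie <- ie + gl * ev$ap_amplitude *
            .event_shape(rel - events$trig_rel[j], ev)
        } else if (stj == "failed") {
          # withdraw the pacemaker drive gradually to avoid a rebound step
          pm_tau <- if (is.null(gate$pacemaker_tau)) ev$ap_rise_tau
                    else gate$pacemaker_tau
          fr <- events$fail_rel[j]
          ie <- ie + gl * ev$ap_amplitude * gate$floor *
            (1 - exp(-fr / pm_tau)) * exp(-(rel - fr) / pm_tau)
        }
      }
    }
    itot <- -gl * (v - el) + alpha[i] + beta[i] * v + ie + i_inject +
      gl * nz + .vgcc_current(v, vgcc, vr)
    v <- v + h * itot / cap
    vtrace[i] <- v
  }
  structure(list(voltage = v, act_dep = ad[n_sub], act_hyp = ah[n_sub],
                 time = state$time + dt, noise = nz, events = events,
                 v_mean = mean(vtrace)),
            class = "ovc_state")
}

#' Steady-state voltage under a fixed light input
#'
#' With gates at their steady drive, the light-gated and leak currents are
#' affine in V, so the fixed point is closed-form; the optional voltage-gated
#' current makes it a scalar root-finding problem.
#'
#' @param config An [ovc_plant_config()] object.
#' @param light An [ovc_light] object.
#' @return Steady-state membrane voltage (mV), noise and events ignored.
#' @export
plant_steady_voltage <- function(config, light) {
  dep <- config$depolarizer; hyp <- config$hyperpolarizer
  vr <- config$resting_potential
  dd <- spectral_drive(light, dep)
  dh <- spectral_drive(light, hyp)
  kd <- dep$max_current * dd / (vr - dep$reversal_potential)
  kh <- hyp$max_current * dh / (vr - hyp$reversal_potential)
  gl <- config$leak_conductance; el <- config$leak_reversal
  bal <- function(v) {
    -gl * (v - el) + kd * (v - dep$reversal_potential) +
      kh * (v - hyp$reversal_potential) + .vgcc_current(v, config$vgcc, vr)
  }
  if (is.null(config$vgcc)) {
    # linear: solve -gl (V - el) + kd (V - Ed) + kh (V - Eh) = 0 directly
    (gl * el - kd * dep$reversal_potential - kh * hyp$reversal_potential) /
      (gl - kd - kh)
  } else {
    lo <- min(dep$reversal_potential, hyp$reversal_potential, el) - 1
    hi <- max(dep$reversal_potential, hyp$reversal_potential, el,
              config$vgcc$reversal) + 1
    stats::uniroot(bal, c(lo, hi), tol = 1e-10)$root
  }
}

#' Steady-state photocurrent at a clamped voltage
#'
#' The light-gated current with gates at steady drive and voltage held fixed
#' (the simulated analog of a voltage-clamp wavelength-step measurement).
#'
#' @inheritParams plant_steady_voltage
#' @param voltage Clamped membrane voltage (mV).
#' @return Steady photocurrent (pA), depolarizing positive.
#' @export
plant_steady_current <- function(config, light, voltage) {
  st <- init_plant_state(config, light)
  st$voltage <- voltage
  photocurrent(st, light, config)
}

#' @export
print.ovc_plant <- function(x, ...) {
  cat("Optical voltage-clamp plant\n")
  cat(sprintf("  C = %.1f pF, g_leak = %.2f nS, rest = %.1f mV\n",
              x$capacitance, x$leak_conductance, x$resting_potential))
  cat(sprintf("  depolarizer:   peak %g nm (sigma %g), %+.1f pA, E_rev %+.0f mV, crosstalk %.2f\n",
              x$depolarizer$peak_wavelength, x$depolarizer$spectral_width,
              x$depolarizer$max_current, x$depolarizer$reversal_potential,
              x$depolarizer$laser_crosstalk))
  cat(sprintf("  hyperpolarizer: peak %g nm (sigma %g), %+.1f pA, E_rev %+.0f mV\n",
              x$hyperpolarizer$peak_wavelength, x$hyperpolarizer$spectral_width,
              x$hyperpolarizer$max_current, x$hyperpolarizer$reversal_potential))
  if (!is.null(x$event_generator))
    cat(sprintf("  events: %s (%g), %g mV, FWHM %g ms\n",
                x$event_generator$kind, x$event_generator$rate_or_interval,
                x$event_generator$ap_amplitude, x$event_generator$ap_fwhm))
  if (x$noise_sd > 0)
    cat(sprintf("  noise: SD %.2f mV, tau %.0f ms\n", x$noise_sd, x$noise_tau))
  invisible(x)
}
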