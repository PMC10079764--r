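#' Tissue presets for the simulated plant
#'
#' Fully specified plant configurations anchored to the quantitative
#' observables reported for each tissue. `bwm` (body-wall muscle) is the
#' reference: resting potential -24 mV; the two photocurrents are balanced so
#' that the imaging-laser crosstalk onto the depolarizer is compensated near
#' 516 nm, the steady wavelength-current relation over 420-580 nm is close to
#' linear with an OLS slope of about -1.21 pA/nm (patch convention), and
#' 470 nm light hyperpolarizes the dark-adapted cell by roughly 16 mV.
#'
#' * `unc13`: as `bwm` but with reduced leak conductance (homeostatically
#'   raised excitability): the same depolarizing drive moves the voltage
#'   further, so holding +5 percent dF/F0 needs a bluer steady wavelength.
#' * `egl19`: as `bwm` plus a depolarization-activated inward current whose
#'   activation midpoint is shifted negative (gain-of-function L-type Ca2+
#'   channel stand-in); the leak reversal is rebalanced so the dark resting
#'   potential is unchanged.
#' * `pharynx`: periodically active muscle firing ~4 Hz action potentials
#'   (free-running fluorescence amplitude ~26 percent dF/F0, FWHM ~120 ms,
#'   rise tau 15 ms), with a regenerative trigger so dynamic clamping can
#'   abort spike attempts.
#' * `dvb`: small GABAergic motor neuron firing one AP every 45 s
#'   (~50 mV, FWHM 500 ms), resting at -49 mV.
#' * `mammalian`: hippocampal-pyramidal-like cell resting at -75 mV with the
#'   hyperpolarizer reversal just above rest (-72 mV, a chloride channel near
#'   its reversal) and strong laser crosstalk onto the depolarizer
#'   (laser alone depolarizes by ~21.5 mV).
#'
#' @param name Preset name: `"bwm"`, `"unc13"`, `"egl19"`, `"pharynx"`,
#'   `"dvb"` or `"mammalian"`.
#' @return An [ovc_plant_config()] object.
#' @export
make_preset <- function(name = c("bwm", "unc13", "egl19", "pharynx", "dvb",
                                 "mammalian")) {
  name <- match.arg(name)
  # Reference channel pair; widths/amplitudes calibrated against the printed
  # wavelength-current anchors (see the methods vignette).
  dep <- ovc_channel(peak_wavelength = 590, spectral_width = 101.3,
                     max_current = 178.5, reversal_potential = 60,
                     activation_tau = 3, laser_crosstalk = 0.05)
  hyp <- ovc_channel(peak_wavelength = 470, spectral_width = 111.6,
                     max_current = -158.2, reversal_potential = -120,
                     activation_tau = 3)
  base <- function(...) {
    args <- list(capacitance = 50, leak_conductance = 2, leak_reversal = -24,
                 resting_potential = -24, depolarizer = dep,
                 hyperpolarizer = hyp, noise_sd = 9.3, noise_tau = 700)
    mod <- list(...)
    args[names(mod)] <- mod
    do.call(ovc_plant_config, args)
  }
  switch(name,
    bwm = base(),
    unc13 = base(leak_conductance = 1.3),
    egl19 = {
      vgcc <- list(gmax = 45, vhalf = -16, slope = 3, reversal = 60)
      # rebalance the leak reversal so the dark fixed point stays at -24 mV
      i_rest <- vgcc$gmax / (1 + exp(-(-24 - vgcc$vhalf) / vgcc$slope))
      base(vgcc = vgcc, leak_reversal = -24 - i_rest / 2)
    },
    pharynx = base(leak_reversal = -50, resting_potential = -50,
                   noise_sd = 0.7,
                   event_generator = ovc_events("periodic_ap", 4,
                                                ap_amplitude = 158,
                                                ap_fwhm = 120,
                                                ap_rise_tau = 15,
                                                align = "clamp"),
                   event_gate = list(vhalf = -38, floor = 0.25,
                                     trigger_ms = 120, pacemaker_tau = 40)),
    dvb = {
      depn <- dep; depn$max_current <- 35
      hypn <- hyp; hypn$max_current <- -31
      base(capacitance = 1.5, leak_conductance = 0.8, leak_reversal = -49,
           resting_potential = -49, depolarizer = depn, hyperpolarizer = hypn,
           noise_sd = 4, event_generator = ovc_events("interval_ap", 45,
                                                      ap_amplitude = 85,
                                                      ap_fwhm = 630,
                                                      ap_rise_tau = 50,
                                                      align = "clamp"),
           event_gate = list(vhalf = -30, floor = 0.45, trigger_ms = 150))
    },
    mammalian = {
      depm <- dep; depm$max_current <- 300; depm$reversal_potential <- 10
      depm$laser_crosstalk <- 0.384
      hypm <- hyp; hypm$max_current <- -300; hypm$reversal_potential <- -72
      base(capacitance = 150, leak_conductance = 4, leak_reversal = -75,
           resting_potential = -75, depolarizer = depm, hyperpolarizer = hypm,
           noise_sd = 3)
    })
}

#' Sensor presets matched to the tissue presets
#'
#' The voltage-to-fluorescence gain differs by tissue: 10 percent dF/F0 per
#' 22 mV in body-wall muscle, per 65 mV in the DVB neuron, and roughly
#' 21 percent per 100 mV in mammalian neurons. The reference voltage (where
#' dF/F0 = 0) is the steady-state voltage under the calibration light
#' (imaging laser plus start wavelength), so clamp targets are relative to
#' the calibration operating point.
#'
#' @inheritParams make_preset
#' @param plant The matching plant configuration (used to place the
#'   reference voltage at the calibration operating point); defaults to
#'   `make_preset(name)`.
#' @param start_wavelength Calibration wavelength (nm).
#' @return An [ovc_sensor_config()] object.
#' @export
make_sensor_preset <- function(name = c("bwm", "unc13", "egl19", "pharynx",
                                        "dvb", "mammalian"),
                               plant = make_preset(name),
                               start_wavelength = default_start_wavelength(name)) {
  name <- match.arg(name)
  dff_per_mv <- switch(name, dvb = 10 / 65, mammalian = 0.21, 10 / 22)
  vref <- plant_steady_voltage(plant,
                               light_input(start_wavelength, 1, TRUE))
  ovc_sensor_config(dff_per_mv = dff_per_mv, reference_voltage = vref)
}

#' Default calibration (compensation) wavelength for a preset
#'
#' The wavelength at which the monochromator drive cancels the laser
#' crosstalk photocurrent at the resting potential, rounded to the
#' monochromator's 0.1 nm resolution. For the mammalian preset the
#' conventional 530 nm compensation is used (full cancellation is not
#' attainable there).
#'
#' @inheritParams make_preset
#' @return Wavelength in nm.
#' @export
default_start_wavelength <- function(name = "bwm") {
  if (identical(name, "mammalian")) return(530)
  plant <- make_preset(name)
  f <- function(l) plant_steady_current(plant, light_input(l, 1, TRUE),
                                        plant$resting_potential)
  round(stats::uniroot(f, c(420, 580), tol = 1e-3)$root, 1)
}

#' Controller presets matched to the tissue presets
#'
#' Integral gain and tolerance band as used per tissue: the step-clamp
#' presets use a +/-1 percent tolerance; the dynamic-clamp presets
#' (`pharynx`, `dvb`) use a strongly increased integral gain and a
#' +/-0.005 percent tolerance so that spontaneous APs are counteracted
#' within a few frames.
#'
#' @inheritParams make_preset
#' @return An [i_controller()] configuration.
#' @export
make_controller_preset <- function(name = c("bwm", "unc13", "egl19",
                                            "pharynx", "dvb", "mammalian")) {
  name <- match.arg(name)
  start <- default_start_wavelength(name)
  if (name %in% c("pharynx", "dvb"))
    i_controller(ki = 4, tolerance = 0.005, start_wavelength = start)
  else
    i_controller(ki = 2.5, tolerance = 1, start_wavelength = start)
}

#' Bundle plant, sensor and controller presets for one tissue
#'
#' @inheritParams make_preset
#' @return A list with elements `plant`, `sensor`, `controller` and `name`.
#' @export
ovc_setup <- function(name = c("bwm", "unc13", "egl19", "pharynx", "dvb",
                               "mammalian")) {
  name <- match.arg(name)
  plant <- make_preset(name)
  controller <- make_controller_preset(name)
  sensor <- make_sensor_preset(name, plant, controller$start_wavelength)
  list(name = name, plant = plant, sensor = sensor, controller = controller)
}

#' Write / read a plant configuration as plain-text YAML
#'
#' Serializes all plant parameters (units: mV, pA, pF, nS, nm, ms) so preset
#' variants can be stored and reloaded.
#'
#' @param config An [ovc_plant_config()] object.
#' @param path File path.
#' @return `write_plant_config` returns `path` invisibly;
#'   `read_plant_config` returns the reconstructed [ovc_plant_config()].
#' @export
write_plant_config <- function(config, path) {
  x <- unclass(config)
  x$depolarizer <- unclass(x$depolarizer)
  x$hyperpolarizer <- unclass(x$hyperpolarizer)
  if (!is.null(x$event_generator)) x$event_generator <- unclass(x$event_generator)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_plant_config
#' @export
read_plant_config <- function(path) {
  x <- yaml::read_yaml(path)
  ev <- NULL
  if (!is.null(x$event_generator))
    ev <- do.call(ovc_events, x$event_generator[c("kind", "rate_or_interval",
                                                  "ap_amplitude", "ap_fwhm",
                                                  "ap_rise_tau")])
  chan <- function(ch)
    do.call(ovc_channel, ch[c("peak_wavelength", "spectral_width",
                              "max_current", "reversal_potential",
                              "activation_tau", "laser_crosstalk")])
  ovc_plant_config(capacitance = x$capacitance,
                   leak_conductance = x$leak_conductance,
                   leak_reversal = x$leak_reversal,
                   resting_potential = x$resting_potential,
                   depolarizer = chan(x$depolarizer),
                   hyperpolarizer = chan(x$hyperpolarizer),
                   noise_sd = x$noise_sd, noise_tau = x$noise_tau,
                   event_generator = ev, vgcc = x$vgcc)
}
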