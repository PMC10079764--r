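#' Fluorescent voltage-sensor configuration
#'
#' Linear voltage-to-fluorescence mapping with multiplicative exponential
#' photobleaching, Gaussian shot noise and ADU quantization. The bleach
#' profile is `a * exp(-b * frame) + c`, applied multiplicatively to the whole
#' signal and normalized to 1 at frame 0.
#'
#' @param dff_per_mv Fluorescence change per mV of depolarization
#'   (percent dF/F0 per mV).
#' @param reference_voltage Voltage at which dF/F0 = 0 (mV); normally the
#'   resting potential.
#' @param photons_per_frame Expected photon count per frame, unbleached, at
#'   the reference voltage.
#' @param bleach_a,bleach_b,bleach_c Bleach-profile parameters: amplitudes
#'   `a`, `c` (relative units) and per-frame decay rate `b` (>= 0).
#' @param adu_per_photon Camera conversion gain (ADU per photon).
#' @param exposure Exposure time per frame (ms).
#' @param frame_period Frame period (ms), >= exposure.
#' @return An object of class `ovc_sensor`.
#' @export
ovc_sensor_config <- function(dff_per_mv, reference_voltage,
                              photons_per_frame = 1.8e6,
                              bleach_a = 0.25, bleach_b = 5e-4,
                              bleach_c = 0.75, adu_per_photon = 1,
                              exposure = 10, frame_period = 10) {
  stopifnot(photons_per_frame > 0, bleach_b >= 0, frame_period >= exposure,
            adu_per_photon > 0)
  structure(list(dff_per_mv = dff_per_mv,
                 reference_voltage = reference_voltage,
                 photons_per_frame = photons_per_frame,
                 bleach_a = bleach_a, bleach_b = bleach_b, bleach_c = bleach_c,
                 adu_per_photon = adu_per_photon, exposure = exposure,
                 frame_period = frame_period),
            class = "ovc_sensor")
}

# Bleach profile normalized to 1 at frame 0.
.bleach_profile <- function(frame, config) {
  (config$bleach_a * exp(-config$bleach_b * frame) + config$bleach_c) /
    (config$bleach_a + config$bleach_c)
}

#' Expected photon count for a frame
#'
#' `photons_per_frame * (1 + dff_per_mv * (V - reference_voltage)/100) *
#' bleach_profile(frame)`, clipped at 0.
#'
#' @param voltage Membrane voltage (mV), vectorized.
#' @param frame Frame index (0-based), vectorized.
#' @param config An [ovc_sensor_config()] object.
#' @return Expected photon count (>= 0).
#' @export
expected_photons <- function(voltage, frame, config) {
  pmax(0, config$photons_per_frame *
         (1 + config$dff_per_mv * (voltage - config$reference_voltage) / 100) *
         .bleach_profile(frame, config))
}

#' Sample one camera frame
#'
#' Gray value `adu_per_photon * round(Normal(N, sqrt(N)))` with
#' `N = expected_photons(...)`: the Gaussian approximation to Poisson photon
#' shot noise (relative noise SD `1/sqrt(N)`), then ADU quantization.
#' Uses R's global RNG stream; `shot_noise = FALSE` gives the noise-free gray.
#'
#' @inheritParams expected_photons
#' @param shot_noise Draw shot noise? (`FALSE` returns the expectation.)
#' @return A one-row data frame with `frame`, `time` (ms) and `gray` (ADU).
#' @export
sample_frame <- function(voltage, frame, config, shot_noise = TRUE) {
  n <- expected_photons(voltage, frame, config)
  ph <- if (shot_noise) stats::rnorm(length(n), n, sqrt(n)) else n
  data.frame(frame = frame, time = frame * config$frame_period,
             gray = pmax(0, round(config$adu_per_photon * ph)))
}
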