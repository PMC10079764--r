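#' Synthetic simultaneous-calibration data sets
#'
#' Emulate the two calibration experiments that anchor the optical-to-
#' electrical conversions, using the reference plant/sensor maps as ground
#' truth plus heteroscedastic measurement scatter (between-animal variation
#' grows towards the extremes, which is why the published regressions use
#' robust standard errors; the noise scale is chosen so the fits land near
#' the published R^2 of 0.8).
#'
#' `simulate_voltage_calibration`: paired (dF/F0 clamp target, measured
#' membrane potential) observations across -5..+5 percent steps. The
#' generating line is `V = reference_voltage + target / dff_per_mv`.
#'
#' `simulate_current_calibration`: paired (wavelength, steady-state clamp
#' current) observations across 420-580 nm with the cell held at its resting
#' potential; currents in the patch convention (inward negative), i.e. the
#' negative of the plant's depolarizing-positive photocurrent.
#'
#' @param n Number of observations (spread evenly over the step grid).
#' @param plant,sensor Reference configurations.
#' @param noise_base,noise_het Baseline and proportional components of the
#'   residual SD (mV or pA): `sd = noise_base + noise_het * |x - center|`.
#' @param seed Optional RNG seed.
#' @return A data frame with columns `x`, `y` and attribute
#'   `"generating_slope"` (the noiseless OLS slope over the design grid).
#' @export
simulate_voltage_calibration <- function(n = 80, plant = make_preset("bwm"),
                                         sensor = make_sensor_preset("bwm"),
                                         noise_base = 2, noise_het = 0.5,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- seq(-5, 5, length.out = 11)
  x <- rep_len(targets, n)
  v_true <- sensor$reference_voltage + x / sensor$dff_per_mv
  y <- v_true + stats::rnorm(n, 0, noise_base + noise_het * abs(x))
  out <- data.frame(x = x, y = y)
  attr(out, "generating_slope") <- 1 / sensor$dff_per_mv
  out
}

#' @rdname simulate_voltage_calibration
#' @export
simulate_current_calibration <- function(n = 72, plant = make_preset("bwm"),
                                         noise_base = 25, noise_het = 0.12,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam_grid <- seq(420, 580, by = 20)
  x <- rep_len(lam_grid, n)
  i_true <- -vapply(x, function(l)
    plant_steady_current(plant, light_input(l, 1, TRUE),
                         plant$resting_potential), 0)
  y <- i_true + stats::rnorm(n, 0, noise_base + noise_het * abs(x - 500))
  out <- data.frame(x = x, y = y)
  i_grid <- -vapply(lam_grid, function(l)
    plant_steady_current(plant, light_input(l, 1, TRUE),
                         plant$resting_potential), 0)
  attr(out, "generating_slope") <-
    unname(stats::coef(stats::lm(i_grid ~ lam_grid))[2])
  out
}
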