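#' Calibration regression with robust standard errors
#'
#' Ordinary least squares `y = a + b x`, with heteroscedasticity-consistent
#' (White/HC0) standard errors and the White test for heteroscedasticity
#' (auxiliary regression of the squared residuals on `x` and `x^2`;
#' `LM = n R^2` against chi-squared with 2 df).
#'
#' @param x,y Numeric vectors, `length >= 3`, `x` not constant.
#' @return An object of class `ovc_calibration`: `intercept`, `slope`,
#'   `robust_se_intercept`, `robust_se_slope`, `r_squared`, `white_test_p`,
#'   `n`.
#' @export
fit_calibration <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant; calibration fit undefined")
  fit <- stats::lm(y ~ x)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  e2 <- stats::resid(fit)^2
  aux <- stats::lm(e2 ~ x + I(x^2))
  lm_stat <- length(x) * summary(aux)$r.squared
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 robust_se_intercept = sqrt(vc[1, 1]),
                 robust_se_slope = sqrt(vc[2, 2]),
                 r_squared = summary(fit)$r.squared,
                 white_test_p = stats::pchisq(lm_stat, df = 2,
                                              lower.tail = FALSE),
                 n = length(x)),
            class = "ovc_calibration")
}

#' @export
print.ovc_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration fit (n = %s): y = %.4g + %.4g x  (R^2 = %.3f)\n",
    if (is.na(x$n)) "?" else x$n, x$intercept, x$slope, x$r_squared))
  if (is.finite(x$robust_se_slope))
    cat(sprintf("  robust (HC0) SEs: intercept %.4g, slope %.4g; White test p = %.3g\n",
                x$robust_se_intercept, x$robust_se_slope, x$white_test_p))
  invisible(x)
}

#' Published default calibration regressions
#'
#' The body-wall-muscle calibration constants: membrane potential as a
#' function of dF/F0 holding value (intercept -30.27 mV, slope 2.25 mV per
#' percent, R^2 0.8, n = 80) and current as a function of wavelength
#' (intercept 607.06 pA, slope -1.21 pA/nm, R^2 0.8, n = 72; patch
#' convention, inward current negative).
#'
#' @param which `"voltage"` (mV vs percent dF/F0) or `"current"` (pA vs nm).
#' @return An `ovc_calibration` object (robust SEs not available).
#' @export
calibration_defaults <- function(which = c("voltage", "current")) {
  which <- match.arg(which)
  p <- if (which == "voltage")
    list(intercept = -30.27, slope = 2.25, n = 80)
  else
    list(intercept = 607.06, slope = -1.21, n = 72)
  structure(list(intercept = p$intercept, slope = p$slope,
                 robust_se_intercept = NA_real_, robust_se_slope = NA_real_,
                 r_squared = 0.8, white_test_p = NA_real_, n = p$n),
            class = "ovc_calibration")
}

#' Convert optical readouts to voltage and current
#'
#' Affine evaluation of a calibration regression: `dff_to_mv` maps percent
#' dF/F0 to membrane potential (mV); `wavelength_to_pa` maps a wavelength
#' (nm) to the equivalent clamp current (pA, patch convention).
#'
#' @param dff dF/F0 in percent (vectorized).
#' @param fit An `ovc_calibration` object.
#' @return Numeric vector.
#' @export
dff_to_mv <- function(dff, fit = calibration_defaults("voltage")) {
  fit$intercept + fit$slope * dff
}

#' @rdname dff_to_mv
#' @param wavelength Wavelength in nm (vectorized).
#' @export
wavelength_to_pa <- function(wavelength,
                             fit = calibration_defaults("current")) {
  fit$intercept + fit$slope * wavelength
}

# Clamp-phase step table of a session: first/last frame index (into
# session$frames) and target of each maximal constant-target run.
.session_steps <- function(session) {
  f <- session$frames
  cl <- which(f$status != "C" & !is.na(f$target_pct))
  if (!length(cl)) stop("session has no clamp phase")
  tg <- f$target_pct[cl]
  r <- rle(tg)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(step = seq_along(r$values), target = r$values,
             first = cl[starts], last = cl[ends])
}

#' Transition time of a clamp step
#'
#' Time from the first frame of the step to the first frame whose deviation
#' from the step target is inside the tolerance band; 0 if the step starts
#' inside. A step that never enters the band is saturated/incomplete and
#' yields `NA` (flagged with attribute `"saturated"`).
#'
#' @param session An `ovc_session` object.
#' @param step_index Which step (1-based; steps are maximal runs of constant
#'   target).
#' @param tolerance Band half-width (percent); defaults to the session
#'   controller's tolerance.
#' @return Transition time in ms.
#' @export
transition_time <- function(session, step_index,
                            tolerance = session$controller$tolerance) {
  steps <- .session_steps(session)
  stopifnot(step_index >= 1, step_index <= nrow(steps))
  s <- steps[step_index, ]
  f <- session$frames[s$first:s$last, ]
  inside <- abs(f$dff_pct - s$target) <= tolerance
  if (!any(inside)) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  f$time_ms[which(inside)[1]] - f$time_ms[1]
}

#' Control-quality metrics of a clamp session
#'
#' Fractions of clamp-phase frames whose control deviation lies inside the
#' tolerance band and inside half of it; per-step transition times; the
#' fraction of frames at the wavelength limits (saturation); and a binned
#' r.m.s. deviation time course with the transition periods excluded.
#'
#' @inheritParams transition_time
#' @param bin_ms Bin width of the r.m.s.d. time course (ms).
#' @return An object of class `ovc_quality`: `within_tol_fraction`,
#'   `within_half_tol_fraction`, `transition_times` (ms, `NA` when
#'   saturated), `saturation_fraction`, `rmsd_timecourse` (data frame with
#'   `bin_start_ms`, `rmsd`).
#' @export
control_quality <- function(session,
                            tolerance = session$controller$tolerance,
                            bin_ms = 100) {
  steps <- .session_steps(session)
  f <- session$frames
  cl <- f$status != "C" & !is.na(f$target_pct)
  dev <- f$dff_pct[cl] - f$target_pct[cl]
  tt <- vapply(steps$step, function(i)
    as.numeric(transition_time(session, i, tolerance)), 0)
  # mask transition periods for the rmsd time course
  keep <- rep(TRUE, sum(cl))
  idx_cl <- which(cl)
  for (i in seq_len(nrow(steps))) {
    if (is.na(tt[i])) { keep[idx_cl %in% steps$first[i]:steps$last[i]] <- FALSE; next }
    n_tr <- ceiling(tt[i] / (1000 / session$protocol$fps))
    if (n_tr > 0)
      keep[match(steps$first[i]:min(steps$first[i] + n_tr, steps$last[i]),
                 idx_cl)] <- FALSE
  }
  t_cl <- f$time_ms[cl] - f$time_ms[cl][1]
  bin <- floor(t_cl / bin_ms)
  ok <- keep & !is.na(dev)
  rmsd <- tapply(dev[ok]^2, bin[ok], function(z) sqrt(mean(z)))
  structure(list(
    within_tol_fraction = mean(abs(dev) <= tolerance, na.rm = TRUE),
    within_half_tol_fraction = mean(abs(dev) <= tolerance / 2, na.rm = TRUE),
    transition_times = tt,
    saturation_fraction = mean(f$status[cl] == "L"),
    rmsd_timecourse = data.frame(
      bin_start_ms = as.numeric(names(rmsd)) * bin_ms,
      rmsd = as.numeric(rmsd))),
    class = "ovc_quality")
}

#' @export
print.ovc_quality <- function(x, ...) {
  cat(sprintf(
    "Control quality: %.1f%% within tolerance, %.1f%% within half tolerance\n",
    100 * x$within_tol_fraction, 100 * x$within_half_tol_fraction))
  cat(sprintf("  saturation: %.2f%% of frames; transitions (ms): %s\n",
              100 * x$saturation_fraction,
              paste(round(x$transition_times), collapse = ", ")))
  invisible(x)
}

#' Detect action potentials in a fluorescence (or voltage) trace
#'
#' Peak detection by topographic prominence on a uniformly sampled trace:
#' local maxima whose prominence exceeds `min_prominence` are kept (the
#' highest peak wins within `min_separation`). Amplitude is measured from
#' the local baseline (the higher of the two flanking minima), duration as
#' full width at half maximum with linear interpolation of the crossings,
#' and the rise time constant from the 10-90 percent span of the rising
#' flank of a saturating exponential (`tau = t_{10-90} / ln 9`).
#'
#' @param time Sample times (ms), uniformly spaced.
#' @param value Trace values (percent dF/F0 or mV).
#' @param min_prominence Minimum peak prominence (same units as `value`).
#' @param min_separation Minimum peak separation (ms).
#' @return A data frame of class `ovc_aps` with columns `peak_time`,
#'   `amplitude`, `fwhm`, `rise_tau` (empty if no peaks qualify).
#' @export
detect_aps <- function(time, value, min_prominence,
                       min_separation = diff(range(time)) / 1e3) {
  n <- length(value)
  empty <- structure(data.frame(peak_time = numeric(0),
                                amplitude = numeric(0), fwhm = numeric(0),
                                rise_tau = numeric(0)),
                     class = c("ovc_aps", "data.frame"))
  if (n < 3) return(empty)
  d <- diff(value)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(empty)
  # prominence: drop to the lowest point between the peak and the nearest
  # higher ground on each side
  prom <- vapply(cand, function(i) {
    left_hi <- which(value[seq_len(i - 1)] > value[i])
    lo <- if (length(left_hi)) max(left_hi) + 1L else 1L
    right_hi <- which(value[(i + 1):n] > value[i])
    hi <- if (length(right_hi)) i + min(right_hi) - 1L else n
    base <- max(min(value[lo:i]), min(value[i:hi]))
    value[i] - base
  }, 0)
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(empty)
  # enforce separation, highest first
  keep <- keep[order(value[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep)
    if (!length(sel) || all(abs(time[i] - time[sel]) >= min_separation))
      sel <- c(sel, i)
  sel <- sort(sel)

  cross_at <- function(i, j, level) {  # linear interpolation between i, j
    time[i] + (level - value[i]) * (time[j] - time[i]) /
      (value[j] - value[i])
  }
  rows <- lapply(sel, function(i) {
    left_hi <- which(value[seq_len(i - 1)] > value[i])
    lo <- if (length(left_hi)) max(left_hi) + 1L else 1L
    right_hi <- which(value[(i + 1):n] > value[i])
    hi <- if (length(right_hi)) i + min(right_hi) - 1L else n
    base <- max(min(value[lo:i]), min(value[i:hi]))
    amp <- value[i] - base
    lvl <- function(frac) base + frac * amp
    walk <- function(level, dir) {
      j <- i
      repeat {
        nxt <- j + dir
        if (nxt < lo || nxt > hi) return(NA_real_)
        if (value[nxt] <= level) return(cross_at(nxt, j, level))
        j <- nxt
      }
    }
    t_half_l <- walk(lvl(0.5), -1L); t_half_r <- walk(lvl(0.5), +1L)
    t10 <- walk(lvl(0.1), -1L); t90 <- walk(lvl(0.9), -1L)
    data.frame(peak_time = time[i], amplitude = amp,
               fwhm = t_half_r - t_half_l,
               rise_tau = (t90 - t10) / log(9))
  })
  structure(do.call(rbind, rows), class = c("ovc_aps", "data.frame"))
}

#' Difference of two pseudo-I/V curves, capacitance-normalized
#'
#' Converts both curves to voltage (via the dF/F0 calibration) and clamp
#' current (via the wavelength calibration), then forms the difference of the
#' cell-intrinsic currents per unit capacitance. The optically applied
#' current mirrors the intrinsic current with opposite sign (at steady state
#' they cancel), so the intrinsic difference `a - b` equals
#' `wavelength_to_pa(b) - wavelength_to_pa(a)`.
#'
#' @param iv_a,iv_b `ovc_pseudo_iv` results on the same target grid
#'   (`a` is typically the mutant, `b` the reference).
#' @param capacitance Membrane capacitance (pF) used for normalization.
#' @param fit_v,fit_i Calibration regressions for voltage and current.
#' @return A data frame with `mv` (voltage axis, mean of the two converted
#'   curves) and `pa_per_pf` (intrinsic current difference density).
#' @export
difference_iv <- function(iv_a, iv_b, capacitance,
                          fit_v = calibration_defaults("voltage"),
                          fit_i = calibration_defaults("current")) {
  stopifnot(nrow(iv_a) == nrow(iv_b),
            isTRUE(all.equal(iv_a$target, iv_b$target)))
  if (capacitance <= 0) stop("capacitance must be positive")
  mv <- (dff_to_mv(iv_a$dff_achieved, fit_v) +
           dff_to_mv(iv_b$dff_achieved, fit_v)) / 2
  d_pa <- wavelength_to_pa(iv_b$wavelength, fit_i) -
    wavelength_to_pa(iv_a$wavelength, fit_i)
  data.frame(mv = mv, pa_per_pf = d_pa / capacitance)
}
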