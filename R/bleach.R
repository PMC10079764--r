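#' Fit the calibration-phase bleaching exponential
#'
#' Nonlinear least-squares fit of `gray ~ a * exp(-b * frame) + c` to the
#' calibration-phase gray values (frame index 0-based), by Levenberg-
#' Marquardt. Initial guesses: `c` from the last-decile mean, `a` from the
#' first-decile mean minus `c`, `b` from a log-linear fit of `gray - c`.
#' Fit quality is `R^2 = 1 - SSE/SSD` (SSD about the mean). On
#' non-convergence a flagged fallback fit (`b = 0`, `c = mean`) is returned,
#' whose low `R^2` signals the failure.
#'
#' @param calibration_grays Numeric vector of gray values (ADU), >= 10.
#' @return An object of class `ovc_bleach_fit` with fields `a`, `b`, `c`,
#'   `r_squared` and `converged`.
#' @export
fit_bleach <- function(calibration_grays) {
  g <- as.numeric(calibration_grays)
  stopifnot(length(g) >= 10)
  k <- seq_along(g) - 1
  n <- length(g)
  dec <- max(1L, n %/% 10)
  c0 <- mean(g[(n - dec + 1):n])
  a0 <- mean(g[1:dec]) - c0
  ssd <- sum((g - mean(g))^2)
  fallback <- structure(list(a = 0, b = 0, c = mean(g), r_squared = 0,
                             converged = FALSE), class = "ovc_bleach_fit")
  if (ssd == 0) {  # constant input: identity correction, perfect fit
    return(structure(list(a = 0, b = 0, c = g[1], r_squared = 1,
                          converged = TRUE), class = "ovc_bleach_fit"))
  }
  b0 <- 1e-3
  pos <- g - c0 > 0
  if (a0 > 0 && sum(pos) >= 3) {
    lf <- stats::lm(log(g[pos] - c0) ~ k[pos])
    if (is.finite(lf$coefficients[2]) && lf$coefficients[2] < 0)
      b0 <- -unname(lf$coefficients[2])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ a * exp(-b * k) + c,
                      start = list(a = a0, b = b0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  p <- stats::coef(fit)
  if (!all(is.finite(p))) return(fallback)
  sse <- sum(stats::resid(fit)^2)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 r_squared = 1 - sse / ssd, converged = TRUE),
            class = "ovc_bleach_fit")
}

#' @export
print.ovc_bleach_fit <- function(x, ...) {
  cat(sprintf(
    "Bleach fit: a = %.4g, b = %.4g per frame, c = %.4g (R^2 = %.4f%s)\n",
    x$a, x$b, x$c, x$r_squared,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Live bleach correction of a gray value
#'
#' Multiplies the raw gray value by the ratio of the fitted exponential
#' offset at frame 0 to the offset at the current frame; the correction is
#' the identity at frame 0 and for a flat profile (`b = 0`).
#'
#' @param gray Raw gray value(s) (ADU).
#' @param frame Frame index (0-based), vectorized.
#' @param fit An [fit_bleach()] result (or any list with `a`, `b`, `c`).
#' @return Bleach-corrected gray value(s).
#' @export
correct_frame <- function(gray, frame, fit) {
  offset <- fit$a * exp(-fit$b * frame) + fit$c
  if (any(offset <= 0)) stop("degenerate bleach fit: non-positive offset")
  gray * (fit$a + fit$c) / offset
}

#' Baseline (F0) from the corrected calibration frames
#'
#' The resting fluorescence F0 is the arithmetic mean of the first
#' `f0_window` bleach-corrected gray values, computed at the last calibration
#' time point.
#'
#' @param corrected_grays Bleach-corrected calibration gray values.
#' @param f0_window Number of leading frames to average (default 50, capped
#'   at the number available).
#' @return An object of class `ovc_baseline` with fields `f0`,
#'   `calibration_frames`, `f0_window`.
#' @export
make_baseline <- function(corrected_grays, f0_window = 50) {
  w <- min(f0_window, length(corrected_grays))
  f0 <- mean(corrected_grays[seq_len(w)])
  if (!is.finite(f0) || f0 <= 0) stop("non-positive baseline F0")
  structure(list(f0 = f0, calibration_frames = length(corrected_grays),
                 f0_window = w), class = "ovc_baseline")
}

#' Bleach-corrected relative fluorescence change
#'
#' `dF/F0 = (F_corrected - F0) / F0 * 100`, in percent.
#'
#' @param gray_corrected Bleach-corrected gray value(s).
#' @param baseline A [make_baseline()] result (or list with `f0 > 0`).
#' @return dF/F0 in percent.
#' @export
compute_dff <- function(gray_corrected, baseline) {
  if (baseline$f0 <= 0) stop("baseline F0 must be positive")
  (gray_corrected - baseline$f0) / baseline$f0 * 100
}
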