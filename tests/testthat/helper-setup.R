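# Shared fixtures: noiseless reference setups and short protocols keep the
# closed-loop tests fast and deterministic.

quiet_setup <- function(name = "bwm") {
  su <- ovc_setup(name)
  su$plant$noise_sd <- 0
  su
}

short_protocol <- function(targets = c(0, -5, 5, 0), frames_per_step = 80,
                           calibration_frames = 300, ...) {
  ovc_protocol(targets = targets, frames_per_step = frames_per_step,
               calibration_frames = calibration_frames, ...)
}

# Minimal session-shaped object for offline-analysis unit tests.
fake_session <- function(dff, target, fps = 100, tolerance = 1,
                         status = NULL) {
  n <- length(dff)
  if (is.null(status)) status <- rep("A", n)
  frames <- data.frame(frame = seq_len(n) - 1L,
                       time_ms = (seq_len(n) - 1L) * 1000 / fps,
                       gray_raw = 0, gray_corr = 0,
                       dff_pct = dff,
                       wavelength_nm = 500,
                       status = status,
                       target_pct = rep_len(target, n),
                       voltage_mv = 0)
  structure(list(frames = frames,
                 controller = i_controller(tolerance = tolerance),
                 protocol = ovc_protocol(targets = unique(target),
                                         frames_per_step = n, fps = fps)),
            class = "ovc_session")
}
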