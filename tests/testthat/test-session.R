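test_that("a seeded run is fully reproducible, down to the results file bytes", {
  su <- ovc_setup("bwm")
  prot <- short_protocol(targets = c(0, -5), frames_per_step = 40,
                         calibration_frames = 200)
  s1 <- run_session(prot, su$plant, su$sensor, su$controller, seed = 42)
  s2 <- run_session(prot, su$plant, su$sensor, su$controller, seed = 42)
  expect_identical(s1$frames, s2$frames)
  p1 <- tempfile(); p2 <- tempfile()
  write_session(s1, p1); write_session(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- run_session(prot, su$plant, su$sensor, su$controller, seed = 43)
  expect_false(identical(s1$frames$gray_raw, s3$frames$gray_raw))
})

test_that("zero controller gain leaves the wavelength at its start value", {
  su <- quiet_setup("bwm")
  ctrl <- su$controller; ctrl$ki <- 0
  ses <- run_session(short_protocol(), su$plant, su$sensor, ctrl, seed = 1)
  cl <- ses$frames[ses$frames$status != "C", ]
  expect_true(all(cl$wavelength_nm == ctrl$start_wavelength))
})

test_that("noiseless four-step clamp reaches every plateau at its fixed point", {
  su <- quiet_setup("bwm")
  prot <- short_protocol(targets = c(0, -5, 5, 0), frames_per_step = 80,
                         calibration_frames = 300)
  ses <- run_session(prot, su$plant, su$sensor, su$controller, seed = 2)
  f <- ses$frames[ses$frames$status != "C", ]
  step_id <- rep(1:4, prot$frames_per_step)
  tol <- su$controller$tolerance
  for (i in 1:4) {
    g <- f[step_id == i, ]
    plateau <- g[(nrow(g) - 19):nrow(g), ]
    expect_lt(max(abs(plateau$dff_pct - g$target_pct[1])), tol + 0.25)
    # plateau wavelength near the analytic fixed point of the static map,
    # within the controller's per-step resolution around the band edge
    lam_star <- wavelength_for_dff(g$target_pct[1], su$plant, su$sensor)
    res_nm <- su$controller$ki * (tol + abs(g$target_pct[1]) * 0.05) +
      abs(g$target_pct[1] - static_dff(lam_star, su$plant, su$sensor))
    dev_dff <- abs(static_dff(mean(plateau$wavelength_nm), su$plant,
                              su$sensor) - g$target_pct[1])
    expect_lt(dev_dff, tol + 0.1)
    expect_lt(abs(mean(plateau$wavelength_nm) - lam_star),
              max(10, res_nm))
  }
})

test_that("every clamp frame carries one status and holds freeze the wavelength", {
  su <- ovc_setup("bwm")
  prot <- short_protocol(targets = c(0, 3), frames_per_step = 60,
                         calibration_frames = 200)
  ses <- run_session(prot, su$plant, su$sensor, su$controller, seed = 9)
  f <- ses$frames
  expect_equal(nrow(f), 200 + 120)  # record count contract
  cl <- f[f$status != "C", ]
  expect_true(all(cl$status %in% c("H", "A", "L")))
  idx <- which(f$status == "H")
  idx <- idx[idx < nrow(f)]
  expect_true(all(f$wavelength_nm[idx + 1] == f$wavelength_nm[idx]))
})

test_that("pseudo-I/V yields 11 monotone steps and an inverse round trip", {
  su <- quiet_setup("bwm")
  prot <- short_protocol(calibration_frames = 300)
  piv <- run_pseudo_iv(c(-5, 5), prot, su$plant, su$sensor, su$controller,
                       frames_per_step = 60, seed = 4)
  expect_equal(nrow(piv), 11)
  expect_equal(piv$target, seq(-5, 5, by = 1))
  expect_true(all(abs(piv$dff_achieved - piv$target) <=
                    su$controller$tolerance + 0.2))
  # red depolarizes: steady wavelength increases with the clamp target
  expect_true(all(diff(piv$wavelength) > 0))
  inv <- run_pseudo_iv(c(-5, 5), prot, su$plant, su$sensor, su$controller,
                       frames_per_step = 60, seed = 5, inverse_of = piv)
  expect_lt(max(abs(inv$dff_achieved - piv$dff_achieved)),
            2 * su$controller$tolerance)
})

test_that("optical current clamp plays waveforms open-loop", {
  su <- quiet_setup("bwm")
  prot <- short_protocol(calibration_frames = 300)
  # zero-intensity waveform: trace stays at baseline
  off <- run_current_clamp(function(t) list(wavelength = 500, intensity = 0),
                           100, prot, su$plant, su$sensor,
                           controller = su$controller, seed = 6)
  f_off <- off$frames[off$frames$status != "C", ]
  expect_lt(max(abs(f_off$dff_pct)), 0.5)
  # slow blue-to-red ramp sweeps dF/F0 monotonically upward
  ramp <- run_current_clamp(cc_ramp(400, 600, 0, 2000), 200, prot,
                            su$plant, su$sensor, controller = su$controller,
                            seed = 7)
  f_r <- ramp$frames[ramp$frames$status != "C", ]
  expect_lt(f_r$dff_pct[30], -3)
  expect_gt(f_r$dff_pct[200], 5)
  expect_gt(cor(f_r$time_ms[30:200], f_r$dff_pct[30:200],
                method = "spearman"), 0.98)
  # a red pulse elicits an action potential in the pharynx preset: with the
  # pacemaker drive set sub-threshold, spikes fire only when the pulse
  # depolarizes the muscle past the regenerative trigger
  sp <- ovc_setup("pharynx")
  sp$plant$event_gate$floor <- 0.03
  sp$plant$event_generator$align <- "clamp"
  pulse <- run_current_clamp(cc_pulse(590, 500, 1000), 250,
                             short_protocol(calibration_frames = 300),
                             sp$plant, sp$sensor, controller = sp$controller,
                             seed = 8)
  f_p <- pulse$frames[pulse$frames$status != "C", ]
  before <- f_p$dff_pct[f_p$time_ms - f_p$time_ms[1] < 500]
  during <- f_p$dff_pct[f_p$time_ms - f_p$time_ms[1] >= 500]
  expect_lt(max(before), 8)
  expect_gt(max(during), 15)
})

test_that("on-the-run target schedules reduce to and extend the step protocol", {
  su <- ovc_setup("bwm")
  prot <- short_protocol(targets = 2, frames_per_step = 60,
                         calibration_frames = 200)
  a <- run_session(prot, su$plant, su$sensor, su$controller, seed = 11)
  b <- on_the_run(data.frame(time_ms = 0, target = 2), 60, prot,
                  su$plant, su$sensor, su$controller, seed = 11)
  expect_identical(a$frames, b$frames)
  # alternating targets: the controller re-enters the band after each change
  su_q <- quiet_setup("bwm")
  sched <- data.frame(time_ms = seq(0, 4500, by = 500),
                      target = rep(c(3, -3), 5))
  ses <- on_the_run(sched, 500, short_protocol(calibration_frames = 300),
                    su_q$plant, su_q$sensor, su_q$controller, seed = 12)
  f <- ses$frames[ses$frames$status != "C", ]
  blocks <- split(seq_len(500), rep(1:10, each = 50))
  for (blk in blocks) {
    dev <- abs(f$dff_pct[blk] - f$target_pct[blk])
    expect_lte(min(dev), su_q$controller$tolerance)
  }
  # recovery from saturation: unreachable then reachable target
  sched2 <- data.frame(time_ms = c(0, 1500), target = c(30, 0))
  ses2 <- on_the_run(sched2, 300, short_protocol(calibration_frames = 300),
                     su_q$plant, su_q$sensor, su_q$controller, seed = 13)
  f2 <- ses2$frames[ses2$frames$status != "C", ]
  expect_true("L" %in% f2$status[1:150])
  expect_true("H" %in% f2$status[151:300])
})

test_that("results files round-trip through the documented text format", {
  su <- ovc_setup("bwm")
  prot <- short_protocol(targets = c(0, -2), frames_per_step = 30,
                         calibration_frames = 100)
  ses <- run_session(prot, su$plant, su$sensor, su$controller, seed = 21)
  path <- tempfile(fileext = ".txt")
  write_session(ses, path)
  back <- read_session(path)
  expect_equal(as.numeric(back$header[["fps"]]), 100)
  expect_equal(as.numeric(back$header[["bleach_r_squared"]]),
               ses$bleach_fit$r_squared, tolerance = 1e-5)
  expect_equal(nrow(back$frames), nrow(ses$frames))
  expect_equal(back$frames$dff_pct, ses$frames$dff_pct, tolerance = 1e-4)
  expect_equal(back$frames$status, ses$frames$status)
})
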