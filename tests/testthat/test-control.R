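test_that("decision-tree controller holds, adapts and clips as specified", {
  cfg <- i_controller(ki = 2, tolerance = 1, start_wavelength = 500)
  st <- init_controller_state(cfg)
  # inside the band: identity, holding
  st1 <- i_step(st, dff = -4.5, target = -5, cfg)
  expect_equal(st1$wavelength, 500)
  expect_equal(st1$status, "holding")
  # outside: lambda moves by ki * e in the signed direction
  st2 <- i_step(st, dff = 0, target = 5, cfg)
  expect_equal(st2$wavelength, 510)
  expect_equal(st2$status, "adapting")
  st2b <- i_step(st, dff = 0, target = -5, cfg)
  expect_equal(st2b$wavelength, 490)
  # polarity flag mirrors the increment direction
  cfg_neg <- i_controller(ki = 2, tolerance = 1, increment_sign = -1,
                          start_wavelength = 500)
  st2c <- i_step(init_controller_state(cfg_neg), dff = 0, target = 5, cfg_neg)
  expect_equal(st2c$wavelength, 490)
  # huge gain clips at the limit and reports saturation
  cfg_hot <- i_controller(ki = 1000, tolerance = 1, start_wavelength = 595)
  st3 <- i_step(init_controller_state(cfg_hot), dff = 0, target = 5, cfg_hot)
  expect_equal(st3$wavelength, 600)
  expect_equal(st3$status, "limit_reached")
  # non-finite measurement: hold and flag
  st4 <- i_step(st, dff = NaN, target = 5, cfg)
  expect_equal(st4$wavelength, 500)
  expect_true(isTRUE(attr(st4, "flagged")))
})

test_that("the controller is idle on any frame inside the tolerance band", {
  set.seed(123)
  for (i in 1:50) {
    tol <- runif(1, 0.1, 2)
    cfg <- i_controller(ki = runif(1, 0.5, 10), tolerance = tol,
                        start_wavelength = runif(1, 420, 580))
    st <- init_controller_state(cfg)
    st$wavelength <- runif(1, cfg$lambda_min, cfg$lambda_max)
    target <- runif(1, -5, 5)
    dff <- target + runif(1, -tol, tol)
    st1 <- i_step(st, dff, target, cfg)
    expect_equal(st1$wavelength, st$wavelength)
    expect_equal(st1$status, "holding")
  }
})

test_that("PID output follows the discrete control law", {
  # zero gains: wavelength pinned to the calibration wavelength
  cfg0 <- pid_controller(kp = 0, ki = 0, kd = 0, ta = 0.01, lambda0 = 520,
                         tolerance = 0)
  st <- init_controller_state(cfg0)
  for (k in 1:5) st <- pid_step(st, dff = rnorm(1), target = 3, cfg0)
  expect_equal(st$wavelength, 520)
  # constant error, kd = 0: u_n = kp e + ki ta n e
  cfg <- pid_controller(kp = 2, ki = 5, kd = 0, ta = 0.01, lambda0 = 500,
                        tolerance = 0)
  st <- init_controller_state(cfg)
  e <- 1.5
  for (n in 1:10) {
    st <- pid_step(st, dff = 0, target = e, cfg)
    expect_equal(st$wavelength, 500 + 2 * e + 5 * 0.01 * n * e)
  }
  # derivative term on the first step after an error jump
  cfgd <- pid_controller(kp = 0, ki = 0, kd = 0.1, ta = 0.01, lambda0 = 500,
                         tolerance = 0)
  std <- init_controller_state(cfgd)
  std <- pid_step(std, dff = 0, target = 2, cfgd)
  expect_equal(std$wavelength, 500 + 0.1 * (2 - 0) / 0.01)
})

test_that("integral action removes the steady-state offset a P-controller leaves", {
  # discrete linear test plant: y_k = G * (lambda_{k-1} - 500)
  g <- 0.1
  run_loop <- function(cfg, n = 600) {
    st <- init_controller_state(cfg)
    y <- 0
    for (k in 1:n) {
      st <- pid_step(st, dff = y, target = 2, cfg)
      y <- g * (st$wavelength - 500)
    }
    2 - y
  }
  e_p <- run_loop(pid_controller(kp = 3, ki = 0, kd = 0, ta = 0.01,
                                 lambda0 = 500, tolerance = 0))
  expect_equal(e_p, 2 / (1 + 3 * g), tolerance = 1e-6)
  e_pi <- run_loop(pid_controller(kp = 3, ki = 20, kd = 0, ta = 0.01,
                                  lambda0 = 500, tolerance = 0), n = 1200)
  expect_lt(abs(e_pi), 1e-3)
})

test_that("Ziegler-Nichols table and derived gains", {
  zn <- zn_tune(10, 1)
  expect_equal(zn$kp, 6)
  expect_equal(zn$tn, 0.5)
  expect_equal(zn$tv, 0.12)
  expect_equal(zn$ki, 12)
  expect_equal(zn$kd, 0.72)
  zn1 <- zn_tune(1, 1)
  expect_equal(zn1$kp, 0.6)
  expect_equal(zn1$ki, 1.2)
  expect_equal(zn1$kd, 0.072)
  expect_error(zn_tune(0, 1))
  expect_error(zn_tune(1, -2))
})

test_that("auto-tuning finds a critical gain and the tuned loop is stable", {
  su <- quiet_setup("bwm")
  res <- find_critical_gain(su$plant, su$sensor, target = 3,
                            lambda0 = su$controller$start_wavelength,
                            frames = 200)
  expect_gt(res$kp_crit, 0)
  expect_gt(res$t_crit, 0)
  zn <- res$tuning
  cfg <- pid_controller(kp = zn$kp, ki = zn$ki, kd = zn$kd, ta = 0.01,
                        lambda0 = su$controller$start_wavelength,
                        tolerance = 0)
  # raw tuned loop at this sampling rate: bounded, zero-mean about target
  run_tuned <- function(kal) {
    st <- init_plant_state(su$plant, light_input(cfg$lambda0, 1, TRUE))
    cs <- init_controller_state(cfg)
    err <- numeric(300)
    for (k in 1:300) {
      li <- light_input(cs$wavelength, 1, TRUE)
      st <- step_plant(st, li, su$plant, dt = 10)
      dff <- su$sensor$dff_per_mv * (st$v_mean - su$sensor$reference_voltage)
      err[k] <- 3 - dff
      if (is.null(kal)) {
        cs <- pid_step(cs, dff, 3, cfg)
      } else {
        out <- pid_step(cs, dff, 3, cfg, kal)
        cs <- out$state; kal <- out$kalman
      }
    }
    err
  }
  err_raw <- run_tuned(NULL)
  expect_true(all(is.finite(err_raw)))
  expect_lt(max(abs(err_raw[101:300])), 3)
  expect_lt(abs(mean(err_raw[251:300])), 0.3)
  # with the sensor-smoothing Kalman filter the step error decays to zero
  err_kal <- run_tuned(kalman_state(x0 = 0, q = 0.05, r = 0.5))
  expect_lt(mean(abs(err_kal[251:300])), 0.05 * mean(abs(err_kal[1:20])))
})

test_that("scalar Kalman filter follows the predict-correct recursion", {
  # perfect prior, no process noise: measurements are ignored
  ks <- kalman_state(x0 = 1.5, p0 = 0, q = 0, r = 0.01)
  for (z in c(10, -3, 7)) {
    ks <- kalman_step(ks, z)
    expect_equal(ks$k_gain, 0)
    expect_equal(ks$x_hat, 1.5)
  }
  # constant measurement: estimate converges to it, variance to the
  # steady-state Riccati solution
  q <- 2e-3; r <- 0.05
  ks <- kalman_state(x0 = 0, q = q, r = r)
  for (i in 1:500) ks <- kalman_step(ks, 4)
  expect_equal(ks$x_hat, 4, tolerance = 1e-6)
  p_star_inf <- (q + sqrt(q^2 + 4 * q * r)) / 2   # prior-variance fixed point
  expect_equal(ks$p, p_star_inf * r / (p_star_inf + r), tolerance = 1e-8)
  expect_equal(ks$p + q, p_star_inf, tolerance = 1e-8)
  expect_equal(ks$k_gain, p_star_inf / (p_star_inf + r), tolerance = 1e-8)
  # near-infinite process noise: the filter trusts the measurement
  ks2 <- kalman_step(kalman_state(x0 = 0, q = 1e9 * 0.01, r = 0.01), 6)
  expect_equal(ks2$x_hat, 6, tolerance = 1e-6)
  # variance convergence is monotone
  ks3 <- kalman_state(x0 = 0, p0 = 1, q = 1e-4, r = 0.01)
  ps <- numeric(50)
  for (i in 1:50) { ks3 <- kalman_step(ks3, 0); ps[i] <- ks3$p }
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(kalman_state(q = 1e-3, r = 0))
})

test_that("Kalman smoothing plugs into the PID loop", {
  cfg <- pid_controller(kp = 1, ki = 2, kd = 0, ta = 0.01, lambda0 = 500,
                        tolerance = 0)
  st <- init_controller_state(cfg)
  ks <- kalman_state(x0 = 0, q = 1e-3, r = 0.05)
  out <- pid_step(st, dff = 0.5, target = 2, cfg, kalman = ks)
  expect_named(out, c("state", "kalman"))
  expect_lt(out$kalman$x_hat, 0.5)   # smoothed toward the prior
  expect_gt(out$kalman$x_hat, 0)
})
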