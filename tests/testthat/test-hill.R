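test_that("hill_value satisfies its defining identities", {
  p <- hill_params(0, 10, 0.02, 2)
  expect_equal(hill_value(p, 0), 0)
  expect_equal(hill_value(p, 0.02), 5) # half saturation at t = E50
  expect_equal(hill_value(p, 1e6), 10, tolerance = 1e-9)

  p2 <- hill_params(-3, 4, 0.05, 1.7)
  expect_equal(hill_value(p2, 0.05), (-3 + 4) / 2)

  # the printed variant does not put the midpoint at E50
  expect_false(isTRUE(all.equal(hill_value(p, 0.02, form = "printed"), 5)))

  expect_error(hill_params(0, 10, 0.02, 0.9), "alpha")
  expect_error(hill_params(0, 10, -1, 2), "E50")
  expect_error(hill_params(5, 5, 0.02, 2), "differ")
})

test_that("analytic velocity agrees with numerical differentiation", {
  for (p in list(hill_params(0, 10, 0.02, 2),
                 hill_params(2, -8, 0.035, 1.4),
                 hill_params(0, 25, 0.06, 3.2))) {
    tt <- seq(1e-4, 0.3, length.out = 500)
    h <- 1e-7
    num <- (hill_value(p, tt + h) - hill_value(p, tt - h)) / (2 * h)
    expect_equal(hill_velocity(p, tt), num, tolerance = 1e-6)
  }
  # velocity vanishes at t -> 0+ for alpha > 1
  p <- hill_params(0, 10, 0.02, 2)
  expect_lt(abs(hill_velocity(p, 1e-12)), 1e-6)
})

test_that("closed-form kinematics match brute-force oracles over a sweep", {
  # oracle: dense-grid maximization for t_peak, uniroot for fraction times
  set.seed(42)
  cases <- expand.grid(alpha = c(1.2, 1.7, 2, 2.8, 4),
                       E50 = c(0.005, 0.02, 0.05, 0.08),
                       amp = c(1, 5, 12, 25))
  for (i in seq_len(nrow(cases))) {
    a <- cases$alpha[i]; e <- cases$E50[i]; A <- cases$amp[i]
    p <- hill_params(0, A, e, a)
    k <- extract_kinematics(p)
    opt <- stats::optimize(function(t) hill_velocity(p, t),
                           interval = c(1e-9, 10 * e), maximum = TRUE,
                           tol = 1e-12)
    expect_equal(k$t_peak, opt$maximum, tolerance = 1e-6)
    expect_equal(k$peak_velocity, opt$objective, tolerance = 1e-9)
    for (f in c(0.02, 0.98)) {
      root <- stats::uniroot(function(t) hill_value(p, t) - f * A,
                             interval = c(1e-12, 1e5), tol = 1e-12)$root
      target <- if (f == 0.02) k$t_start else k$t_end
      expect_equal(target, root, tolerance = 1e-6)
    }
  }
})

test_that("worked example: E50 = 20 ms, alpha = 2", {
  p <- hill_params(0, 10, 0.02, 2)
  k <- extract_kinematics(p)
  expect_equal(k$t_end, 0.14, tolerance = 1e-9)
  expect_equal(k$t_start, 0.02 / 7, tolerance = 1e-9)
  expect_equal(k$duration, 0.137143, tolerance = 1e-5)
  expect_equal(k$amplitude, 9.6)
  expect_equal(k$t_peak, 0.02 / sqrt(3), tolerance = 1e-9)
  expect_equal(k$peak_velocity, 324.76, tolerance = 1e-4)
  expect_equal(hill_velocity(p, 0.0115470), 324.76, tolerance = 1e-4)
})

test_that("kinematics scale as the Hill form dictates", {
  p1 <- hill_params(0, 10, 0.02, 2)
  p2 <- hill_params(0, 10, 0.04, 2) # E50 doubled
  k1 <- extract_kinematics(p1); k2 <- extract_kinematics(p2)
  expect_equal(k2$t_start, 2 * k1$t_start)
  expect_equal(k2$t_peak, 2 * k1$t_peak)
  expect_equal(k2$duration, 2 * k1$duration)
  expect_equal(k2$peak_velocity, k1$peak_velocity / 2)
  expect_equal(k2$amplitude, k1$amplitude)

  # duration increasing in E50; peak velocity increasing in |Emax - E0|
  durs <- sapply(c(0.01, 0.02, 0.04, 0.08), function(e)
    extract_kinematics(hill_params(0, 10, e, 2))$duration)
  expect_true(all(diff(durs) > 0))
  vels <- sapply(c(2, 5, 10, 20), function(A)
    extract_kinematics(hill_params(0, A, 0.02, 2))$peak_velocity)
  expect_true(all(diff(vels) > 0))
})

test_that("fitting exact Hill samples is self-consistent", {
  p <- hill_params(0, 10, 0.02, 2)
  tt <- seq(0.004, 0.25, by = 0.004)
  f <- fit_hill(hill_value(p, tt), tt)
  expect_true(f$converged)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$params$Emax, 10, tolerance = 1e-6)
  expect_equal(f$params$E50, 0.02, tolerance = 1e-5)
  expect_equal(f$params$alpha, 2, tolerance = 1e-4)

  expect_error(fit_hill(rep(1, 20), (1:20) * 0.004), "flat")
  expect_error(fit_hill(1:4, (1:4) * 0.004), "6 samples")
})

test_that("fitting recovers kinematics despite noise and window padding", {
  p <- hill_params(0, 10, 0.02, 2)
  kt <- extract_kinematics(p)
  dt <- 0.004
  tt <- seq(dt, 0.4, by = dt)
  y0 <- ifelse(tt < 0.1, 0, hill_value(p, tt - 0.1)) # 100 ms pre-plateau

  # noiseless with shifted origin: exact recovery through the onset estimate
  f0 <- fit_hill(y0, tt)
  k0 <- extract_kinematics(f0$params)
  expect_equal(k0$amplitude, kt$amplitude, tolerance = 1e-6)
  expect_equal(k0$peak_velocity, kt$peak_velocity, tolerance = 1e-5)

  # with measurement noise the fit stays excellent
  set.seed(7)
  f1 <- fit_hill(y0 + rnorm(length(y0), 0, 0.1), tt)
  expect_gt(f1$r_squared, 0.99)

  # downsampled to 50 Hz: amplitude and peak velocity within 5% of 250 Hz
  keep <- seq(1, length(tt), by = 5)
  f2 <- fit_hill(y0[keep], tt[keep])
  k2 <- extract_kinematics(f2$params)
  k1 <- extract_kinematics(f0$params)
  expect_lt(abs(k2$amplitude - k1$amplitude) / k1$amplitude, 0.05)
  expect_lt(abs(k2$peak_velocity - k1$peak_velocity) / k1$peak_velocity, 0.05)
})

test_that("noiseless parameter recovery holds at every rate down to 50 Hz", {
  for (fs in c(250, 125, 100, 50)) {
    for (amp in c(3, 12)) {
      p <- hill_params_for(amp, 40 + 100 * sqrt(amp - 0.99), 2.2)
      kt <- extract_kinematics(p)
      dt <- 1 / fs
      tt <- seq(dt, 0.08 + kt$t_end + 0.08, by = dt)
      y <- ifelse(tt < 0.08, 0, hill_value(p, tt - 0.08))
      k <- extract_kinematics(fit_hill(y, tt)$params)
      expect_lt(abs(k$amplitude - kt$amplitude) / kt$amplitude, 0.005)
      expect_lt(abs(k$peak_velocity - kt$peak_velocity) / kt$peak_velocity,
                0.01)
    }
  }
})

test_that("the fit beats the threshold estimator at 50 Hz peak velocity", {
  # 100 noisy replicates of one saccade, onset phase random within a sampling
  # period (the phase is what quantization-limited estimators are blind to)
  amp <- 10; vpk <- 320
  fit_v <- th_v <- numeric(100)
  for (i in 1:100) {
    set.seed(i)
    jit <- runif(1, 0, 0.02)
    tr <- single_step_trace(amp, vpk, 2, fs = 50, noise_sd = 0.1,
                            fix_s = 0.3 + jit)
    seg <- detect_saccades(tr)
    if (nrow(seg) != 1) { fit_v[i] <- NA; th_v[i] <- NA; next }
    seg <- project_trajectory(seg, tr)
    kin <- saccade_kinematics(seg, tr)
    fit_v[i] <- kin$peak_velocity[kin$method == "fit"]
    th_v[i] <- kin$peak_velocity[kin$method == "threshold"]
  }
  # the fit is unbiased where the sampled maximum is systematically low
  expect_lt(abs(median(fit_v, na.rm = TRUE) - vpk), 10)
  expect_gt(vpk - median(th_v, na.rm = TRUE), 50)
  expect_lt(median(abs(fit_v - vpk), na.rm = TRUE),
            median(abs(th_v - vpk), na.rm = TRUE))
})

test_that("tidiers expose the fit in broom style", {
  p <- hill_params(0, 10, 0.02, 2)
  tt <- seq(0.004, 0.25, by = 0.004)
  f <- fit_hill(hill_value(p, tt), tt)
  td <- tidy(f)
  expect_equal(td$term, c("E0", "Emax", "E50", "alpha", "t0"))
  gl <- glance(f)
  expect_equal(gl$n, length(tt))
  au <- augment(f)
  expect_equal(au$.resid, au$position - au$.fitted)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(f, "velocity"), "ggplot")
})
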