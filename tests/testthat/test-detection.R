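test_that("numerical velocity matches hand arithmetic for both stencils", {
  tr <- gaze_trace(time = (0:9) * 0.004,
                   azimuth = c(0, 1, 3, rep(3, 7)),
                   elevation = rep(0, 10))
  fd <- compute_velocity(tr, "first_difference")
  expect_false(fd$valid[1])
  expect_equal(fd$speed[2], 250)
  expect_equal(fd$speed[3], 500)

  cd <- compute_velocity(tr, "central_difference")
  expect_false(cd$valid[1])
  expect_false(cd$valid[10])
  expect_equal(cd$speed[2], 3 / 0.008) # 375 deg/s at the middle sample

  still <- gaze_trace((0:9) * 0.004, rep(1, 10), rep(-2, 10))
  expect_true(all(compute_velocity(still)$speed[2:9] == 0))
})

test_that("a single sigmoid step yields one segment with the right amplitude", {
  tr <- single_step_trace(amplitude = 10)
  seg <- detect_saccades(tr)
  expect_equal(nrow(seg), 1)
  # centroid-to-centroid distance is the asymptotic displacement (10 / 0.96)
  expect_equal(seg$nominal_amplitude, 10 / 0.96, tolerance = 0.02)
  expect_equal(seg$direction_deg, 0, tolerance = 1)
  expect_lt(seg$window_start, seg$onset_index)
  expect_gt(seg$window_end, seg$offset_index)
})

test_that("noise alone does not trigger detection (fixed seed)", {
  set.seed(99)
  tt <- (0:499) * 0.004
  tr <- gaze_trace(tt, rnorm(500, 0, 0.05), rnorm(500, 0, 0.05),
                   sampling_frequency = 250)
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("detection is invariant to constant offsets and ordered in time", {
  set.seed(3)
  cfg <- synth_config(n_saccades = 10, noise_sd = 0.05, seed = 3)
  tr <- generate_trace(cfg)$trace
  seg <- detect_saccades(tr)
  shifted <- gaze_trace(tr$time, tr$azimuth + 4, tr$elevation - 7,
                        sampling_frequency = sampling_frequency(tr))
  seg2 <- detect_saccades(shifted)
  expect_equal(nrow(seg2), nrow(seg))
  expect_true(all(diff(seg$onset_index) > 0))
})

test_that("two well-separated steps produce two segments in order", {
  p <- hill_params_for(8, 300, 2)
  tt <- seq(0, 1.4, by = 0.004)
  disp <- ifelse(tt < 0.3, 0, hill_value(p, tt - 0.3)) +
    ifelse(tt < 0.9, 0, hill_value(p, tt - 0.9))
  tr <- gaze_trace(tt, disp, rep(0, length(tt)), sampling_frequency = 250)
  seg <- detect_saccades(tr)
  expect_equal(nrow(seg), 2)
  expect_lt(seg$offset_index[1], seg$onset_index[2])
})

test_that("projection maps the trajectory onto the movement axis", {
  # purely horizontal: projection equals azimuth minus pre-centroid azimuth
  tr <- single_step_trace(amplitude = 10, direction_deg = 0)
  seg <- project_trajectory(detect_saccades(tr), tr)
  pr <- seg$projection[[1]]
  pre_az <- seg$pre_azimuth[1]
  expect_equal(pr$position, tr$azimuth[pr$index] - pre_az, tolerance = 1e-12)
  expect_lt(abs(pr$position[1]), 0.1)
  expect_equal(pr$position[nrow(pr)], seg$nominal_amplitude[1],
               tolerance = 0.05)

  # oblique 45-deg direction: final projected value ~ full length, not /sqrt(2)
  tro <- single_step_trace(amplitude = 10, direction_deg = 45)
  sego <- project_trajectory(detect_saccades(tro), tro)
  pro <- sego$projection[[1]]
  expect_equal(pro$position[nrow(pro)], 10 / 0.96, tolerance = 0.1)

  # displacement orthogonal to the axis contributes nothing
  seg1 <- detect_saccades(tr)
  u <- c(cos(seg1$direction_deg[1] * pi / 180),
         sin(seg1$direction_deg[1] * pi / 180))
  orth <- c(-u[2], u[1])
  expect_equal(sum(orth * u), 0)
})

test_that("microsaccade filtering splits without losing segments", {
  seg <- tibble::tibble(saccade = 1:3, nominal_amplitude = c(0.5, 1.5, 8))
  out <- filter_microsaccades(seg, 1)
  expect_equal(out$kept$nominal_amplitude, c(1.5, 8))
  expect_equal(out$discarded$nominal_amplitude, 0.5)
  expect_equal(nrow(out$kept) + nrow(out$discarded), 3)

  all_kept <- filter_microsaccades(seg, 0)
  expect_equal(nrow(all_kept$kept), 3)

  none <- filter_microsaccades(seg[0, ], 1)
  expect_equal(nrow(none$kept), 0)
  expect_equal(nrow(none$discarded), 0)
})

test_that("horizontal selection keeps a closed cone about 0 and 180 deg", {
  seg <- tibble::tibble(direction_deg = c(0, 10, 170, 90, 15, -15, 180, -170))
  kept <- select_horizontal(seg, 15)
  expect_equal(kept$direction_deg, c(0, 10, 170, 15, -15, 180, -170))
  expect_equal(nrow(select_horizontal(seg, 90)), nrow(seg))
})

test_that("threshold kinematics underestimate duration and peak velocity", {
  amp <- 10; vpk <- 320; alpha <- 2
  p <- hill_params_for(amp, vpk, alpha)
  true_dur <- extract_kinematics(p)$duration

  tr <- single_step_trace(amp, vpk, alpha, fs = 250)
  seg <- project_trajectory(detect_saccades(tr), tr)
  th <- threshold_kinematics(seg, tr, velocity_threshold = 50)
  # endpoints are marked inside the 50 deg/s crossings: shorter than 2-98%
  expect_lt(th$duration, true_dur)
  # a sampled maximum cannot exceed the analytic peak
  expect_lte(th$peak_velocity, vpk + 1e-9)

  # peak velocity non-increasing as sampling frequency drops (noiseless)
  vpks <- sapply(c(1, 2, 5), function(f) {
    trf <- downsample(tr, f)
    segf <- project_trajectory(detect_saccades(trf), trf)
    threshold_kinematics(segf, trf)$peak_velocity
  })
  expect_true(all(diff(vpks) <= 1e-9))

  # no supra-threshold sample -> NA kinematics
  slow <- single_step_trace(amplitude = 1.5, peak_velocity = 45)
  segs <- project_trajectory(detect_saccades(slow), slow)
  ths <- threshold_kinematics(segs, slow, velocity_threshold = 200)
  expect_true(is.na(ths$peak_velocity))
})

test_that("endpoint quantization error equals one sampling period", {
  expect_equal(duration_quantization_error_ms(200), 5)
  expect_equal(duration_quantization_error_ms(50), 20)
})
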