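# Small fixture builders shared across test files.

# single Hill-shaped step between two fixations, noise-free by default
single_step_trace <- function(amplitude = 10, peak_velocity = 320, alpha = 2,
                              fs = 250, fix_s = 0.2, noise_sd = 0,
                              direction_deg = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- hill_params_for(amplitude, peak_velocity, alpha)
  dur <- p$E50 * ((0.98 / 0.02)^(1 / alpha) - (0.02 / 0.98)^(1 / alpha))
  t_total <- fix_s + dur + fix_s
  tt <- seq(0, t_total, by = 1 / fs)
  disp <- ifelse(tt < fix_s, 0, hill_value(p, tt - fix_s))
  th <- direction_deg * pi / 180
  az <- disp * cos(th)
  el <- disp * sin(th)
  if (noise_sd > 0) {
    az <- az + rnorm(length(az), 0, noise_sd)
    el <- el + rnorm(length(el), 0, noise_sd)
  }
  gaze_trace(tt, az, el, sampling_frequency = fs)
}

# points lying exactly on a given model curve
exact_points <- function(model_id, params, constants = NULL,
                         amplitudes = seq(1.5, 24, length.out = 40)) {
  tibble::tibble(
    amplitude = amplitudes,
    peak_velocity = saccfit:::ms_predict(model_id, params, amplitudes,
                                         constants)
  )
}
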