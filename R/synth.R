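#' Hill parameters realizing a requested amplitude and peak velocity
#'
#' Inverts the closed-form kinematics: with the dimensionless peak factor
#' `h(alpha) = alpha c^(alpha-1) / (1 + c^alpha)^2`, `c = ((alpha-1)/(alpha+1))^(1/alpha)`,
#' the peak velocity of a Hill trajectory is `|Emax - E0| / E50 * h(alpha)`,
#' so `E50 = |Emax - E0| h(alpha) / v_peak`. `E0 = 0` and
#' `Emax = amplitude / 0.96`, so the reported 2-98% amplitude equals the
#' requested one.
#'
#' @param amplitude Target 2-98% amplitude, deg (> 0).
#' @param peak_velocity Target peak velocity, deg/s (> 0).
#' @param alpha Hill slope exponent (> 1).
#' @return A [hill_params()].
#' @examples
#' p <- hill_params_for(9.6, 324.76, 2)
#' extract_kinematics(p)[, c("amplitude", "peak_velocity")]
#' @export
hill_params_for <- function(amplitude, peak_velocity, alpha) {
  stopifnot(amplitude > 0, peak_velocity > 0, alpha > 1)
  Emax <- amplitude / 0.96
  E50 <- Emax * hill_peak_factor(alpha) / peak_velocity
  hill_params(E0 = 0, Emax = Emax, E50 = E50, alpha = alpha)
}

#' Configuration for the synthetic gaze generator
#'
#' Defines the study conditions the generator emulates: fixations separated
#' by sigmoid-shaped saccadic displacements whose peak velocity follows a
#' main-sequence law, sampled at a configurable frequency with additive
#' Gaussian position noise.
#'
#' Defaults: a fixed-sqrt law `v = VA + V sqrt(A - A_th)` with `VA = 40`
#' deg/s, `A_th = 1` deg and `V = 100`; Hill exponents uniform on
#' `[1.6, 2.6]`; amplitudes log-uniform on `[1, 25]` deg (short saccades
#' predominate, as in natural viewing); directions uniform around the clock,
#' kept within a `+/- 25` deg screen box; fixation durations uniform on
#' `[0.25, 0.45]` s; 250 Hz sampling.
#'
#' @param n_saccades Number of saccades.
#' @param sampling_frequency Hz.
#' @param noise_sd Additive position noise SD per axis, deg.
#' @param law Main-sequence law: list with `model_id`, `params` and optional
#'   `constants`, as in a [fit_main_sequence()] result.
#' @param alpha_range Interval for the Hill exponent draw.
#' @param amplitude_range Log-uniform amplitude support, deg.
#' @param relative_noise Multiplicative velocity noise SD for
#'   [generate_points()].
#' @param fixation_duration Interval for fixation durations, s.
#' @param duration_law `c(d0, d1)`: expected 2-98% duration in seconds is
#'   `d0 + d1 * amplitude`; used only to sanity-bound alpha draws (a draw is
#'   rejected if its implied duration falls outside 0.4-2.5x this value).
#' @param position_box Half-width of the admissible gaze box, deg.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_saccades = 100, sampling_frequency = 250,
                         noise_sd = 0.1,
                         law = list(model_id = "fixed_sqrt",
                                    params = c(V = 100),
                                    constants = list(VA = 40, A_th = 1)),
                         alpha_range = c(1.6, 2.6),
                         amplitude_range = c(1, 25),
                         relative_noise = 0.15,
                         fixation_duration = c(0.25, 0.45),
                         duration_law = c(d0 = 0.06, d1 = 0.006),
                         position_box = 25,
                         seed = 1) {
  stopifnot(n_saccades >= 1, sampling_frequency > 0, noise_sd >= 0,
            relative_noise >= 0, all(amplitude_range > 0))
  structure(
    list(n_saccades = n_saccades, sampling_frequency = sampling_frequency,
         noise_sd = noise_sd, law = law, alpha_range = alpha_range,
         amplitude_range = amplitude_range, relative_noise = relative_noise,
         fixation_duration = fixation_duration, duration_law = duration_law,
         position_box = position_box, seed = seed),
    class = "synth_config"
  )
}

law_velocity <- function(law, amplitude) {
  ms_predict(law$model_id, law$params, amplitude, law$constants)
}

draw_alpha <- function(config, amplitude, peak_velocity) {
  expect_dur <- config$duration_law[[1]] + config$duration_law[[2]] * amplitude
  for (i in 1:20) {
    a <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
    p <- hill_params_for(amplitude, peak_velocity, a)
    dur <- p$E50 * ((0.98 / 0.02)^(1 / a) - (0.02 / 0.98)^(1 / a))
    if (dur >= 0.4 * expect_dur && dur <= 2.5 * expect_dur) return(a)
  }
  a
}

#' Generate a synthetic gaze trace with known ground truth
#'
#' Builds a continuous 2-D gaze path of alternating fixations and Hill-shaped
#' saccades: each saccade's sigmoid starts at its onset and keeps relaxing
#' toward its asymptote through the following fixation, so position is
#' continuous everywhere. Peak velocities follow the configured main-sequence
#' law; per-sample Gaussian noise is added to both coordinates. Deterministic
#' for a given config seed.
#'
#' @param config A [synth_config()].
#' @return A list with `trace` (a [gaze_trace()]) and `truth`, a tibble of
#'   per-saccade ground truth: `onset_time`, `amplitude` (2-98%),
#'   `duration`, `peak_velocity`, `direction_deg`, `alpha`, `E50`.
#' @export
generate_trace <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_saccades
  amp <- exp(stats::runif(n, log(config$amplitude_range[1]),
                          log(config$amplitude_range[2])))
  vel <- law_velocity(config$law, amp)
  fix <- stats::runif(n + 1L, config$fixation_duration[1],
                      config$fixation_duration[2])

  params <- vector("list", n)
  dur <- numeric(n)
  for (i in seq_len(n)) {
    a <- draw_alpha(config, amp[i], vel[i])
    params[[i]] <- hill_params_for(amp[i], vel[i], a)
    k <- params[[i]]
    dur[i] <- k$E50 * ((0.98 / 0.02)^(1 / k$alpha) - (0.02 / 0.98)^(1 / k$alpha))
  }

  # saccade onset times: fixation, then sigmoid until 98% + next fixation
  onsets <- numeric(n)
  t_cursor <- fix[1]
  for (i in seq_len(n)) {
    onsets[i] <- t_cursor
    t_cursor <- t_cursor + dur[i] + fix[i + 1L]
  }
  t_total <- t_cursor

  # directions, bounded to the screen box
  box <- config$position_box
  base <- matrix(0, n + 1L, 2)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    dE <- params[[i]]$Emax
    ok <- FALSE
    for (try in 1:200) {
      th <- stats::runif(1, 0, 2 * pi)
      target <- base[i, ] + dE * c(cos(th), sin(th))
      if (all(abs(target) <= box)) { ok <- TRUE; break }
    }
    if (!ok) th <- atan2(-base[i, 2], -base[i, 1])
    theta[i] <- th
    # position actually reached when the next saccade starts
    gap <- if (i < n) onsets[i + 1L] - onsets[i] else t_total - onsets[i]
    reached <- hill_value(params[[i]], gap)
    base[i + 1L, ] <- base[i, ] + reached * c(cos(th), sin(th))
  }

  fs <- config$sampling_frequency
  time <- seq(0, t_total, by = 1 / fs)
  seg <- findInterval(time, onsets) # 0 = before first saccade
  az <- numeric(length(time)); el <- numeric(length(time))
  for (i in seq_len(n)) {
    sel <- seg == i
    if (!any(sel)) next
    disp <- hill_value(params[[i]], time[sel] - onsets[i])
    az[sel] <- base[i, 1] + disp * cos(theta[i])
    el[sel] <- base[i, 2] + disp * sin(theta[i])
  }
  if (config$noise_sd > 0) {
    az <- az + stats::rnorm(length(az), 0, config$noise_sd)
    el <- el + stats::rnorm(length(el), 0, config$noise_sd)
  }
  truth <- tibble::tibble(
    saccade = seq_len(n),
    onset_time = onsets,
    amplitude = amp,
    duration = dur,
    peak_velocity = vel,
    direction_deg = theta * 180 / pi,
    alpha = vapply(params, `[[`, numeric(1), "alpha"),
    E50 = vapply(params, `[[`, numeric(1), "E50")
  )
  list(trace = gaze_trace(time, az, el, sampling_frequency = fs),
       truth = truth)
}

#' Generate main-sequence points directly from a law
#'
#' Bypasses trace generation for fast model studies: amplitudes are drawn
#' log-uniform from the configured range and peak velocities are the law's
#' values perturbed multiplicatively, `v = law(A) (1 + eps)`,
#' `eps ~ N(0, relative_noise)`.
#'
#' @param config A [synth_config()]; uses `n_saccades`, `amplitude_range`,
#'   `law`, `relative_noise` and `seed`.
#' @return A tibble with `amplitude` and `peak_velocity`.
#' @export
generate_points <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_saccades
  amp <- exp(stats::runif(n, log(config$amplitude_range[1]),
                          log(config$amplitude_range[2])))
  v <- law_velocity(config$law, amp)
  if (config$relative_noise > 0) {
    v <- v * (1 + stats::rnorm(n, 0, config$relative_noise))
  }
  tibble::tibble(amplitude = amp, peak_velocity = pmax(v, 1e-6))
}
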