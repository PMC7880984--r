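#' Angular speed of a gaze trace
#'
#' Numerical differentiation of the 2-D gaze position. The backward
#' first-difference form is `||X(t) - X(t-1)|| / dt`; the two-point central
#' difference is `||X(t+1) - X(t-1)|| / (2 dt)`, which has no phase lag and is
#' the default for event detection. Samples where the stencil is undefined
#' (trace boundaries, or neighbours flagged invalid) are marked invalid.
#'
#' @param trace A [gaze_trace()].
#' @param method `"central_difference"` (default) or `"first_difference"`.
#' @return A tibble with columns `time`, `speed` (deg/s) and `valid`, the same
#'   length as the trace, with attribute `method`.
#' @export
compute_velocity <- function(trace,
                             method = c("central_difference",
                                        "first_difference")) {
  method <- match.arg(method)
  n <- nrow(trace)
  if (sum(trace$valid) < 3L) stop("trace too short for differentiation", call. = FALSE)
  dt <- 1 / sampling_frequency(trace)
  az <- trace$azimuth
  el <- trace$elevation
  speed <- rep(NA_real_, n)
  if (method == "first_difference") {
    disp <- sqrt(diff(az)^2 + diff(el)^2)
    speed[-1L] <- disp / dt
    ok <- c(FALSE, trace$valid[-n] & trace$valid[-1L])
  } else {
    disp <- sqrt((az[-(1:2)] - az[1:(n - 2)])^2 +
                 (el[-(1:2)] - el[1:(n - 2)])^2)
    speed[2:(n - 1)] <- disp / (2 * dt)
    ok <- c(FALSE, trace$valid[1:(n - 2)] & trace$valid[-(1:2)], FALSE)
  }
  speed[!ok] <- NA_real_
  out <- tibble::tibble(time = trace$time, speed = speed, valid = ok)
  attr(out, "method") <- method
  out
}

# moving-average copy of the trace used only for event detection
smooth_trace <- function(trace, window) {
  if (window <= 1L) return(trace)
  k <- rep(1 / window, window)
  az <- as.numeric(stats::filter(trace$azimuth, k, sides = 2))
  el <- as.numeric(stats::filter(trace$elevation, k, sides = 2))
  ok <- is.finite(az) & is.finite(el) & trace$valid
  new_gaze_trace(
    tibble::tibble(time = trace$time,
                   azimuth = ifelse(ok, az, trace$azimuth),
                   elevation = ifelse(ok, el, trace$elevation),
                   valid = trace$valid),
    sampling_frequency = sampling_frequency(trace),
    eye = attr(trace, "eye")
  )
}

# contiguous runs of TRUE -> two-column matrix of start/end indices
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect saccades by velocity thresholding
#'
#' Contiguous runs of supra-threshold speed become candidate saccades; runs
#' separated by less than `min_intersaccadic_ms` are merged (a noisy velocity
#' dip should not split one saccade in two). The sub-threshold intervals
#' before and after each candidate are its flanking fixations; their per-axis
#' medians are the fixation centroids, whose distance is the nominal amplitude
#' and whose connecting line defines the movement direction. Each saccade gets
#' an analysis window padded beyond onset/offset (needed to anchor the plateau
#' ends of a trajectory fit) but never crossing a neighbouring saccade.
#' Candidates without a usable flanking fixation are dropped with a warning.
#'
#' For thresholding only, velocity is computed on a copy of the trace smoothed
#' with a `smooth_ms` moving average, and supra-threshold runs shorter than
#' `min_duration_ms` are discarded: differentiation amplifies per-sample
#' position noise in proportion to the sampling rate, and without these two
#' guards white measurement noise alone would cross a 20 deg/s threshold at
#' high sampling frequencies. Kinematic estimation (trajectory fitting, the
#' threshold baseline) always works on the raw samples.
#'
#' @param trace A [gaze_trace()].
#' @param velocity_threshold Detection threshold in deg/s (default 20).
#' @param min_intersaccadic_ms Merge supra-threshold runs closer than this, ms.
#' @param min_duration_ms Discard supra-threshold runs shorter than this, ms.
#' @param smooth_ms Moving-average span of the detection copy, ms (0 disables).
#' @param pad_samples,pad_ms Analysis-window pad beyond onset/offset: the
#'   larger of `pad_samples` samples and `pad_ms` milliseconds is used.
#' @param velocity_method Differentiation scheme, see [compute_velocity()].
#' @return A tibble of saccade segments, one row per saccade: onset/offset
#'   sample indices, window bounds, flanking-fixation centroids and spans,
#'   `nominal_amplitude` (deg) and `direction_deg` (0 = rightward,
#'   counterclockwise positive).
#' @export
detect_saccades <- function(trace, velocity_threshold = 20,
                            min_intersaccadic_ms = 20,
                            min_duration_ms = 12, smooth_ms = 20,
                            pad_samples = 5, pad_ms = 20,
                            velocity_method = "central_difference") {
  stopifnot(velocity_threshold > 0)
  fs <- sampling_frequency(trace)
  window <- max(1L, 2L * floor(fs * smooth_ms / 1000 / 2) + 1L)
  vel <- compute_velocity(smooth_trace(trace, window), velocity_method)
  above <- vel$valid & vel$speed >= velocity_threshold
  runs <- true_runs(above)
  empty <- tibble::tibble(
    saccade = integer(), onset_index = integer(), offset_index = integer(),
    window_start = integer(), window_end = integer(),
    pre_azimuth = double(), pre_elevation = double(),
    pre_start = integer(), pre_end = integer(),
    post_azimuth = double(), post_elevation = double(),
    post_start = integer(), post_end = integer(),
    nominal_amplitude = double(), direction_deg = double()
  )
  if (nrow(runs) == 0L) return(empty)

  # merge runs whose gap is below the intersaccadic minimum
  gap_samp <- ceiling(min_intersaccadic_ms / 1000 * fs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] - 1L < gap_samp) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  min_run <- max(1L, as.integer(ceiling(min_duration_ms / 1000 * fs)))
  merged <- merged[merged[, "end"] - merged[, "start"] + 1L >= min_run, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(empty)

  pad <- max(as.integer(pad_samples), as.integer(ceiling(pad_ms / 1000 * fs)))
  n <- nrow(trace)
  rows <- vector("list", nrow(merged))
  dropped <- 0L
  for (i in seq_len(nrow(merged))) {
    on <- merged[i, "start"]; off <- merged[i, "end"]
    pre_lo  <- if (i == 1L) 1L else merged[i - 1L, "end"] + 1L
    pre_hi  <- on - 1L
    post_lo <- off + 1L
    post_hi <- if (i == nrow(merged)) n else merged[i + 1L, "start"] - 1L
    pre_ok  <- pre_hi >= pre_lo
    post_ok <- post_hi >= post_lo
    if (!pre_ok || !post_ok) { dropped <- dropped + 1L; next }
    pre_idx  <- pre_lo:pre_hi
    post_idx <- post_lo:post_hi
    pre_idx  <- pre_idx[trace$valid[pre_idx]]
    post_idx <- post_idx[trace$valid[post_idx]]
    if (!length(pre_idx) || !length(post_idx)) { dropped <- dropped + 1L; next }
    pre_az  <- stats::median(trace$azimuth[pre_idx])
    pre_el  <- stats::median(trace$elevation[pre_idx])
    post_az <- stats::median(trace$azimuth[post_idx])
    post_el <- stats::median(trace$elevation[post_idx])
    amp <- sqrt((post_az - pre_az)^2 + (post_el - pre_el)^2)
    dir <- atan2(post_el - pre_el, post_az - pre_az) * 180 / pi
    rows[[i]] <- tibble::tibble(
      onset_index = as.integer(on), offset_index = as.integer(off),
      window_start = max(if (pre_ok) pre_lo else 1L, on - pad),
      window_end = min(if (post_ok) post_hi else n, off + pad),
      pre_azimuth = pre_az, pre_elevation = pre_el,
      pre_start = min(pre_idx), pre_end = max(pre_idx),
      post_azimuth = post_az, post_elevation = post_el,
      post_start = min(post_idx), post_end = max(post_idx),
      nominal_amplitude = amp, direction_deg = dir
    )
  }
  if (dropped > 0L) {
    warning(dropped, " candidate saccade(s) dropped for lack of a flanking fixation",
            call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, saccade = dplyr::row_number(), .before = 1L)
}

#' Project saccade trajectories onto the fixation-to-fixation line
#'
#' The straight motion from the pre- to the post-saccadic fixation defines the
#' movement axis. Every window sample, re-origined at the pre-fixation
#' centroid, is projected onto the unit vector toward the post-fixation
#' centroid, giving a signed scalar trajectory (deg) that starts near 0 and
#' ends near the nominal amplitude.
#'
#' @param segments Segment tibble from [detect_saccades()].
#' @param trace The source [gaze_trace()].
#' @return `segments` with a list-column `projection`, each element a tibble
#'   with `index`, `time`, `position` (deg along the movement axis) and `valid`.
#' @export
project_trajectory <- function(segments, trace) {
  proj <- purrr::pmap(
    list(segments$window_start, segments$window_end,
         segments$pre_azimuth, segments$pre_elevation,
         segments$post_azimuth, segments$post_elevation,
         segments$nominal_amplitude),
    function(w0, w1, pa, pe, qa, qe, amp) {
      if (amp <= .Machine$double.eps) {
        stop("degenerate segment: fixation centroids coincide", call. = FALSE)
      }
      u <- c(qa - pa, qe - pe) / amp
      idx <- w0:w1
      tibble::tibble(
        index = idx,
        time = trace$time[idx],
        position = (trace$azimuth[idx] - pa) * u[1] +
                   (trace$elevation[idx] - pe) * u[2],
        valid = trace$valid[idx]
      )
    }
  )
  dplyr::mutate(segments, projection = proj)
}

#' Filter micro-saccades by amplitude
#'
#' Splits detected segments at an eccentricity threshold (default 1 deg, the
#' conventional micro-saccade bound). Discarded rows are returned for audit,
#' never silently lost.
#'
#' @param segments Segment tibble with `nominal_amplitude`.
#' @param amplitude_threshold Minimum amplitude kept, deg.
#' @return A list with tibbles `kept` and `discarded`.
#' @export
filter_microsaccades <- function(segments, amplitude_threshold = 1) {
  keep <- segments$nominal_amplitude >= amplitude_threshold
  list(kept = segments[keep, , drop = FALSE],
       discarded = segments[!keep, , drop = FALSE])
}

#' Select horizontal saccades
#'
#' Keeps segments whose movement direction lies within `half_angle_deg` of
#' horizontal (0 or 180 deg); the boundary is inclusive.
#'
#' @param segments Segment tibble with `direction_deg`.
#' @param half_angle_deg Half-width of the accepted cone, deg (default 15).
#' @return The filtered tibble.
#' @export
select_horizontal <- function(segments, half_angle_deg = 15) {
  d <- abs(((segments$direction_deg + 180) %% 360) - 180) # distance from 0
  off_horizontal <- pmin(d, 180 - d)
  segments[off_horizontal <= half_angle_deg, , drop = FALSE]
}

#' Threshold-based saccade kinematics (baseline method)
#'
#' The conventional sampling estimator used as comparison: start and end are
#' the first and last samples whose speed exceeds `velocity_threshold` within
#' the analysis window, amplitude is the projected displacement between them,
#' duration their time difference, and peak velocity the maximum velocity
#' sample in the window. All three inherit the sampling grid's quantization:
#' each endpoint can be wrong by up to one sampling period, and the sampled
#' maximum underestimates the true peak.
#'
#' @param segments Projected segment tibble (see [project_trajectory()]).
#' @param trace The source [gaze_trace()].
#' @param velocity_threshold Endpoint-marking threshold in deg/s (default 50).
#' @param velocity_method Differentiation scheme for the velocity trace.
#' @return A tibble with one row per segment: `saccade`, `amplitude` (deg),
#'   `duration` (s), `peak_velocity` (deg/s), `start_index`, `end_index`.
#'   Segments with no supra-threshold sample yield NA kinematics.
#' @export
threshold_kinematics <- function(segments, trace, velocity_threshold = 50,
                                 velocity_method = "central_difference") {
  vel <- compute_velocity(trace, velocity_method)
  purrr::pmap_dfr(
    list(segments$saccade, segments$projection),
    function(id, pr) {
      sp <- vel$speed[pr$index]
      ok <- which(vel$valid[pr$index] & sp >= velocity_threshold)
      if (!length(ok)) {
        return(tibble::tibble(saccade = id, amplitude = NA_real_,
                              duration = NA_real_, peak_velocity = NA_real_,
                              start_index = NA_integer_, end_index = NA_integer_))
      }
      s <- ok[1]; e <- ok[length(ok)]
      tibble::tibble(
        saccade = id,
        amplitude = abs(pr$position[e] - pr$position[s]),
        duration = pr$time[e] - pr$time[s],
        peak_velocity = max(sp[vel$valid[pr$index]], na.rm = TRUE),
        start_index = pr$index[s], end_index = pr$index[e]
      )
    }
  )
}

#' Worst-case endpoint timing error of threshold marking
#'
#' A threshold crossing almost never coincides with a sample acquisition, so
#' each marked endpoint can be off by up to one sampling period: 5 ms at
#' 200 Hz, 20 ms at 50 Hz.
#'
#' @param sampling_frequency Hz (vectorized).
#' @return Worst-case per-endpoint error in milliseconds.
#' @export
duration_quantization_error_ms <- function(sampling_frequency) {
  stopifnot(all(sampling_frequency > 0))
  1000 / sampling_frequency
}
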