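#' Screen geometry for pixel-to-degree conversion
#'
#' Describes the display and viewing position needed to convert on-screen
#' pixel coordinates into visual angles. The default center is the geometric
#' center of the screen; gaze at the center maps to azimuth = elevation = 0.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical screen size in centimeters.
#' @param distance_cm Viewing distance from the eyes to the screen plane, cm.
#' @param center_px Optional length-2 numeric, the pixel that maps to
#'   straight-ahead (defaults to the geometric center of the screen).
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' screen_geometry(1920, 1080, 125, 77, 100)
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            distance_cm,
                            center_px = c(width_px / 2, height_px / 2)) {
  vals <- c(width_px, height_px, width_cm, height_cm, distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen dimensions and the viewing distance must be strictly positive",
         call. = FALSE)
  }
  if (length(center_px) != 2L || any(!is.finite(center_px))) {
    stop("`center_px` must be two finite pixel coordinates", call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         distance_cm = distance_cm, center_px = as.numeric(center_px)),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm))
  invisible(x)
}

#' Read screen geometry from a YAML or key=value config file
#'
#' Accepts either a YAML mapping or a flat `key=value` file with keys
#' `width_px`, `height_px`, `width_cm`, `height_cm`, `distance_cm` and an
#' optional `center_px` (two numbers).
#'
#' @param path Path to the config file.
#' @return A [screen_geometry()] object.
#' @export
read_screen_geometry <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(cfg) || !is.list(cfg)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    kv <- strsplit(lines, "=", fixed = TRUE)
    cfg <- stats::setNames(
      lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), "[ ,]+")[[1]])),
      vapply(kv, function(p) trimws(p[1]), character(1))
    )
  }
  need <- c("width_px", "height_px", "width_cm", "height_cm", "distance_cm")
  if (!all(need %in% names(cfg))) {
    stop("geometry config is missing keys: ",
         paste(setdiff(need, names(cfg)), collapse = ", "), call. = FALSE)
  }
  args <- lapply(cfg[need], function(v) as.numeric(v)[1])
  names(args) <- need
  if (!is.null(cfg$center_px)) args$center_px <- as.numeric(unlist(cfg$center_px))
  do.call(screen_geometry, args)
}

#' Convert screen-pixel coordinates to visual angles
#'
#' Each axis is converted independently: the pixel offset from the screen
#' center is turned into centimeters via the physical pixel pitch and into an
#' angle with `atan(offset / distance)`. Rightward and upward are positive;
#' screen pixel y grows downward, so elevation is `atan((cy - y) / D)`.
#'
#' @param x_px,y_px Pixel coordinates (vectorized).
#' @param geometry A [screen_geometry()].
#' @return A tibble with columns `azimuth` and `elevation`, in degrees.
#' @examples
#' g <- screen_geometry(1920, 1080, 125, 77, 100)
#' pixels_to_degrees(960, 540, g) # screen center -> (0, 0)
#' @export
pixels_to_degrees <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  px_cm_x <- geometry$width_cm / geometry$width_px
  px_cm_y <- geometry$height_cm / geometry$height_px
  dx_cm <- (x_px - geometry$center_px[1]) * px_cm_x
  dy_cm <- (geometry$center_px[2] - y_px) * px_cm_y
  tibble::tibble(
    azimuth   = atan2(dx_cm, geometry$distance_cm) * 180 / pi,
    elevation = atan2(dy_cm, geometry$distance_cm) * 180 / pi
  )
}

new_gaze_trace <- function(df, sampling_frequency, eye = "unknown") {
  out <- tibble::new_tibble(df, class = "gaze_trace", nrow = nrow(df))
  attr(out, "sampling_frequency") <- sampling_frequency
  attr(out, "eye") <- eye
  out
}

#' Construct a gaze trace
#'
#' A gaze trace is a tibble with one row per sample and columns `time` (s,
#' strictly increasing, uniformly spaced), `azimuth` and `elevation` (deg) and
#' a logical `valid` flag (tracked vs. lost samples). The sampling frequency
#' is carried as an attribute and available via [sampling_frequency()].
#'
#' @param time Sample timestamps in seconds, strictly increasing and
#'   uniformly spaced.
#' @param azimuth,elevation Gaze angles in degrees.
#' @param valid Logical per-sample validity mask; defaults to finiteness of
#'   both coordinates.
#' @param sampling_frequency Hz; inferred from the median timestamp spacing
#'   when omitted.
#' @param eye One of `"left"`, `"right"`, `"unknown"`.
#' @return A `gaze_trace` tibble.
#' @export
gaze_trace <- function(time, azimuth, elevation,
                       valid = is.finite(azimuth) & is.finite(elevation),
                       sampling_frequency = NULL,
                       eye = c("unknown", "left", "right")) {
  eye <- match.arg(eye)
  n <- length(time)
  if (length(azimuth) != n || length(elevation) != n || length(valid) != n) {
    stop("time, azimuth, elevation and valid must have the same length", call. = FALSE)
  }
  if (n < 10L) stop("a gaze trace needs at least 10 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (is.null(sampling_frequency)) sampling_frequency <- 1 / stats::median(dt)
  valid <- valid & is.finite(azimuth) & is.finite(elevation)
  new_gaze_trace(
    tibble::tibble(time = as.numeric(time), azimuth = as.numeric(azimuth),
                   elevation = as.numeric(elevation), valid = valid),
    sampling_frequency = sampling_frequency, eye = eye
  )
}

#' Sampling frequency of a gaze trace
#' @param trace A `gaze_trace`.
#' @return Frequency in Hz.
#' @export
sampling_frequency <- function(trace) {
  f <- attr(trace, "sampling_frequency")
  if (is.null(f)) 1 / stats::median(diff(trace$time)) else f
}

#' Read a gaze trace from delimited text
#'
#' Expects a UTF-8 delimited file (comma or tab, autodetected) with a header
#' naming columns `time`, `x` and `y`; an optional `eye` column is honoured.
#' Positions may be given in degrees (azimuth/elevation) or in screen pixels;
#' pixel input requires a [screen_geometry()]. Non-finite samples and, for
#' pixel input, samples outside the screen area are flagged invalid in the
#' `valid` mask, never dropped.
#'
#' @param path Path to the file.
#' @param dialect `"degrees"` or `"pixels"`.
#' @param geometry A [screen_geometry()], required for pixel input.
#' @return A `gaze_trace` tibble in degrees.
#' @export
read_gaze_trace <- function(path, dialect = c("degrees", "pixels"),
                            geometry = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "pixels" && is.null(geometry)) {
    stop("pixel input requires a screen geometry", call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("time", "x", "y")
  if (!all(need %in% names(df))) {
    stop("trace file must have header columns time, x, y (missing: ",
         paste(setdiff(need, names(df)), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(df) < 10L) stop("trace has fewer than 10 samples", call. = FALSE)
  if (any(diff(df$time) <= 0)) {
    stop("timestamps are not strictly increasing", call. = FALSE)
  }
  eye <- "unknown"
  if ("eye" %in% names(df)) {
    lab <- unique(stats::na.omit(df$eye))
    if (length(lab) == 1L && lab %in% c("left", "right")) eye <- lab
  }
  valid <- is.finite(df$x) & is.finite(df$y)
  if (dialect == "pixels") {
    on_screen <- valid &
      df$x >= 0 & df$x <= geometry$width_px &
      df$y >= 0 & df$y <= geometry$height_px
    ang <- pixels_to_degrees(ifelse(valid, df$x, 0), ifelse(valid, df$y, 0),
                             geometry)
    gaze_trace(df$time, ang$azimuth, ang$elevation, valid = on_screen,
               eye = eye)
  } else {
    gaze_trace(df$time, ifelse(valid, df$x, NA_real_),
               ifelse(valid, df$y, NA_real_), valid = valid, eye = eye)
  }
}

#' Write a gaze trace to delimited text
#'
#' Writes columns `time`, `x`, `y` (degrees dialect) so that the file can be
#' re-read with [read_gaze_trace()]. Invalid samples are written as empty
#' fields.
#'
#' @param trace A `gaze_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_trace <- function(trace, path) {
  out <- tibble::tibble(
    time = trace$time,
    x = ifelse(trace$valid, trace$azimuth, NA_real_),
    y = ifelse(trace$valid, trace$elevation, NA_real_)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Downsample a gaze trace by pure decimation
#'
#' Keeps every `factor`-th sample starting at index 1 (no anti-alias
#' filtering), emulating a slower eye tracker: a 250 Hz trace decimated by
#' factors 2 to 8 yields 125, 83.3, 62.5, 50, 41.7, 35.7 and 31.3 Hz.
#'
#' @param trace A `gaze_trace`.
#' @param factor Integer decimation factor, >= 1.
#' @return A `gaze_trace` at `sampling_frequency / factor`.
#' @export
downsample <- function(trace, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  }
  if (factor == 1L) return(trace)
  idx <- seq(1L, nrow(trace), by = as.integer(factor))
  new_gaze_trace(trace[idx, , drop = FALSE],
                 sampling_frequency = sampling_frequency(trace) / factor,
                 eye = attr(trace, "eye"))
}
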