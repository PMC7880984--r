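#' The nine main-sequence model identifiers
#'
#' Amplitude (deg) to peak velocity (deg/s) models, grouped by number of free
#' parameters:
#' one-parameter `slope` (`y = a x`), `sqrt` (`y = V sqrt(x)`) and
#' `fixed_sqrt` (`y = VA + V sqrt(x - A_th)`, with `VA` and `A_th` constants
#' taken from the data, not fitted); two-parameter `line` (`y = a x + b`),
#' `power_law` (`y = m x^V`) and `log_log` (`y = exp(V log x + Q)`); and
#' three-parameter `cubic` (the conventional name for the printed polynomial
#' `y = a x^2 + b x + c`), `exponential` (`y = V (1 - exp(-(x - A0)/k))`) and
#' `sigmoid` (`y = Amax / (1 + (V50/x)^alpha)`).
#'
#' @format A character vector of length 9.
#' @export
mainseq_models <- c("slope", "line", "cubic", "sqrt", "fixed_sqrt",
                    "power_law", "log_log", "exponential", "sigmoid")

ms_n_params <- c(slope = 1L, line = 2L, cubic = 3L, sqrt = 1L,
                 fixed_sqrt = 1L, power_law = 2L, log_log = 2L,
                 exponential = 3L, sigmoid = 3L)

ms_predict <- function(model_id, params, x, constants = NULL) {
  p <- params
  switch(model_id,
    slope = p[["a"]] * x,
    line = p[["a"]] * x + p[["b"]],
    cubic = p[["a"]] * x^2 + p[["b"]] * x + p[["c"]],
    sqrt = p[["V"]] * sqrt(x),
    fixed_sqrt = constants[["VA"]] + p[["V"]] * sqrt(x - constants[["A_th"]]),
    power_law = p[["m"]] * x^p[["V"]],
    log_log = exp(p[["V"]] * log(x) + p[["Q"]]),
    exponential = p[["V"]] * (1 - exp(-(x - p[["A0"]]) / p[["k"]])),
    sigmoid = p[["Amax"]] / (1 + (p[["V50"]] / x)^p[["alpha"]]),
    stop("unknown model: ", model_id, call. = FALSE)
  )
}

ms_check_domain <- function(model_id, x, constants = NULL) {
  bad <- switch(model_id,
    fixed_sqrt = any(x < constants[["A_th"]]),
    log_log = any(x <= 0),
    power_law = any(x < 0),
    sigmoid = any(x < 0),
    sqrt = any(x < 0),
    FALSE
  )
  if (bad) {
    constraint <- switch(model_id,
      fixed_sqrt = paste0("requires amplitude >= A_th = ", constants[["A_th"]]),
      log_log = "requires amplitude > 0",
      "requires amplitude >= 0")
    stop("model `", model_id, "` ", constraint, call. = FALSE)
  }
  invisible(TRUE)
}

# core estimator on raw vectors; returns list(params, converged, n_used)
ms_fit_params <- function(x, y, model_id, constants = NULL) {
  n_excluded <- 0L
  if (model_id == "fixed_sqrt") {
    if (is.null(constants)) constants <- list(VA = 40, A_th = 1)
    keep <- x > constants[["A_th"]]
    n_excluded <- sum(!keep)
    x <- x[keep]; y <- y[keep]
  }
  p <- ms_n_params[[model_id]]
  if (length(x) < p + 1L) {
    stop("model `", model_id, "` needs at least ", p + 1L, " points", call. = FALSE)
  }
  converged <- TRUE
  params <- switch(model_id,
    slope = c(a = sum(x * y) / sum(x^2)),
    line = {
      cf <- stats::coef(stats::lm.fit(cbind(x = x, b = 1), y))
      c(a = unname(cf[1]), b = unname(cf[2]))
    },
    cubic = {
      cf <- stats::coef(stats::lm.fit(cbind(x^2, x, 1), y))
      c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]))
    },
    sqrt = {
      ms_check_domain("sqrt", x)
      c(V = sum(sqrt(x) * y) / sum(x))
    },
    fixed_sqrt = {
      s <- sqrt(x - constants[["A_th"]])
      c(V = sum(s * (y - constants[["VA"]])) / sum(s^2))
    },
    log_log = {
      ms_check_domain("log_log", x)
      if (any(y <= 0)) stop("log_log requires positive velocities", call. = FALSE)
      cf <- stats::coef(stats::lm.fit(cbind(lx = log(x), 1), log(y)))
      c(V = unname(cf[1]), Q = unname(cf[2]))
    },
    power_law = {
      ms_check_domain("log_log", x) # same positivity needs for the init
      cf <- stats::coef(stats::lm.fit(cbind(log(x), 1), log(pmax(y, 1e-12))))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ m * x^V, data = data.frame(x = x, y = y),
                          start = list(m = exp(unname(cf[2])), V = unname(cf[1])),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) { converged <- FALSE; c(m = exp(cf[2]), V = unname(cf[1])) }
      else {
        converged <- isTRUE(fit$convInfo$isConv)
        cf2 <- stats::coef(fit); c(m = cf2[["m"]], V = cf2[["V"]])
      }
    },
    exponential = {
      st <- list(V = max(y) * 1.1, A0 = 0, k = 10)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ V * (1 - exp(-(x - A0) / k)),
                          data = data.frame(x = x, y = y), start = st,
                          lower = c(V = 1e-6, A0 = -Inf, k = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) { converged <- FALSE; unlist(st) }
      else {
        converged <- isTRUE(fit$convInfo$isConv)
        cf <- stats::coef(fit); c(V = cf[["V"]], A0 = cf[["A0"]], k = cf[["k"]])
      }
    },
    sigmoid = {
      st <- list(Amax = max(y) * 1.2, V50 = stats::median(x), alpha = 2)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ Amax / (1 + (V50 / x)^alpha),
                          data = data.frame(x = x, y = y), start = st,
                          lower = c(Amax = 1e-6, V50 = 1e-6, alpha = 0.1),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) { converged <- FALSE; unlist(st) }
      else {
        converged <- isTRUE(fit$convInfo$isConv)
        cf <- stats::coef(fit)
        c(Amax = cf[["Amax"]], V50 = cf[["V50"]], alpha = cf[["alpha"]])
      }
    },
    stop("unknown model: ", model_id, call. = FALSE)
  )
  list(params = params, constants = constants, converged = converged,
       n_used = length(x), n_excluded = n_excluded)
}

ms_r_squared <- function(model_id, params, constants, x, y) {
  if (model_id == "fixed_sqrt") {
    keep <- x >= constants[["A_th"]]
    x <- x[keep]; y <- y[keep]
  }
  yhat <- ms_predict(model_id, params, x, constants)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Fit one main-sequence model to amplitude/peak-velocity points
#'
#' Least-squares estimation of the chosen model. Models linear in their
#' parameters (`slope`, `line`, `cubic`, `sqrt`, `fixed_sqrt`) are solved in
#' closed form; `log_log` is an ordinary regression of `log y` on `log x`
#' (the transformation is the point of that model, so its loss intentionally
#' differs from `power_law`'s); `power_law`, `exponential` and `sigmoid` use
#' Levenberg-Marquardt with data-driven initializations (a log-log regression
#' for the power law; `V = 1.1 max(y)`, `A0 = 0`, `k = 10` for the
#' exponential; `Amax = 1.2 max(y)`, `V50 = median(x)`, `alpha = 2` for the
#' sigmoid). For `fixed_sqrt`, points at or below `A_th` are outside the
#' model's domain and are excluded from the fit (count reported).
#'
#' @param points A data frame with columns `amplitude` (deg) and
#'   `peak_velocity` (deg/s).
#' @param model_id One of [mainseq_models].
#' @param constants For `fixed_sqrt`: list with `VA` (deg/s) and `A_th`
#'   (deg); see [compute_fixed_sqrt_constants()]. Defaults to
#'   `list(VA = 40, A_th = 1)`.
#' @return An object of class `mainseq_fit` with the parameter vector, plain
#'   and adjusted R-squared (computed on the untransformed velocities), point
#'   counts and a convergence flag.
#' @examples
#' pts <- tibble::tibble(amplitude = c(1, 4, 9), peak_velocity = c(100, 200, 300))
#' fit_main_sequence(pts, "sqrt")
#' @export
fit_main_sequence <- function(points, model_id = mainseq_models,
                              constants = NULL) {
  model_id <- match.arg(model_id)
  x <- points$amplitude; y <- points$peak_velocity
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0) || any(y <= 0)) {
    stop("amplitudes and peak velocities must be strictly positive", call. = FALSE)
  }
  res <- ms_fit_params(x, y, model_id, constants)
  r2 <- ms_r_squared(model_id, res$params, res$constants, x, y)
  p <- ms_n_params[[model_id]]
  n <- res$n_used
  structure(
    list(model_id = model_id, params = res$params, constants = res$constants,
         r_squared = r2,
         r_squared_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         n_points = n, n_excluded = res$n_excluded,
         converged = res$converged,
         data = tibble::tibble(amplitude = x, peak_velocity = y)),
    class = "mainseq_fit"
  )
}

#' @export
print.mainseq_fit <- function(x, ...) {
  cat(sprintf("<mainseq_fit> %s: %s | adj. R2 = %.4f on %d points\n",
              x$model_id,
              paste(names(x$params), signif(x$params, 5), sep = " = ",
                    collapse = ", "),
              x$r_squared_adjusted, x$n_points))
  invisible(x)
}

#' Evaluate a fitted main-sequence model on an amplitude grid
#'
#' @param fit A `mainseq_fit`.
#' @param amplitudes Amplitude grid, deg; must lie in the model's domain
#'   (`>= A_th` for `fixed_sqrt`, `> 0` for log-like models).
#' @return Peak velocities, deg/s.
#' @export
evaluate_model <- function(fit, amplitudes) {
  ms_check_domain(fit$model_id, amplitudes, fit$constants)
  ms_predict(fit$model_id, fit$params, amplitudes, fit$constants)
}

#' @export
predict.mainseq_fit <- function(object, amplitude, ...) {
  evaluate_model(object, amplitude)
}

#' Tidy and summarize main-sequence fits
#'
#' `tidy()` gives one row per fitted parameter (constants of `fixed_sqrt` are
#' not free parameters and are excluded); `glance()` a one-row model summary.
#'
#' @param x A `mainseq_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mainseq_fit
#' @export
tidy.mainseq_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.mainseq_fit
#' @method glance mainseq_fit
#' @export
glance.mainseq_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, r_squared = x$r_squared,
                 r_squared_adjusted = x$r_squared_adjusted,
                 n_points = x$n_points, n_excluded = x$n_excluded,
                 converged = x$converged)
}

#' Data-driven constants for the fixed sqrt model
#'
#' `VA` is the average peak velocity of saccades at the micro-saccade
#' threshold amplitude `A_th`: the mean over points with
#' `|amplitude - A_th| <= band`. With no points in the band the configured
#' default (40 deg/s, the conventional peak velocity of 1-degree saccades) is
#' used with a warning.
#'
#' @param points Data frame with `amplitude` and `peak_velocity`.
#' @param A_th Threshold amplitude, deg (default 1).
#' @param band Half-width of the averaging band, deg (default 0.25).
#' @param default_VA Fallback when no point lies in the band, deg/s.
#' @return A list with `VA` and `A_th`.
#' @export
compute_fixed_sqrt_constants <- function(points, A_th = 1, band = 0.25,
                                         default_VA = 40) {
  sel <- abs(points$amplitude - A_th) <= band
  if (!any(sel)) {
    warning("no points within ", band, " deg of A_th = ", A_th,
            "; using default VA = ", default_VA, " deg/s", call. = FALSE)
    return(list(VA = default_VA, A_th = A_th))
  }
  list(VA = mean(points$peak_velocity[sel]), A_th = A_th)
}

#' Default amplitude grid for curve comparison
#'
#' 1 to 25 deg in 0.25-deg steps: the analyzed amplitude range, starting at
#' the micro-saccade bound where every model (including `fixed_sqrt` with
#' `A_th = 1`) is defined.
#'
#' @param from,to,by Grid limits and step, deg.
#' @return Numeric vector of amplitudes.
#' @export
mainseq_grid <- function(from = 1, to = 25, by = 0.25) seq(from, to, by = by)
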