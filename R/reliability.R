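#' Symmetric MAPE between two fitted main-sequence curves
#'
#' Mean over the amplitude grid of `|ya - yb| / ((ya + yb)/2) * 100`: the
#' percentage change between two estimations of the same curve. The symmetric
#' denominator (pair mean) is used because the two fits are equally valid
#' estimates — neither is a privileged reference — which also makes the
#' statistic symmetric in its arguments.
#'
#' @param fit_a,fit_b `mainseq_fit` objects sharing a domain on `grid`.
#' @param grid Amplitude grid, deg (default [mainseq_grid()]).
#' @return MAPE in percent.
#' @export
curve_mape <- function(fit_a, fit_b, grid = mainseq_grid()) {
  ya <- evaluate_model(fit_a, grid)
  yb <- evaluate_model(fit_b, grid)
  mean(abs(ya - yb) / ((ya + yb) / 2)) * 100
}

mape_from_curves <- function(ya, yb) {
  mean(abs(ya - yb) / ((ya + yb) / 2)) * 100
}

# all pairwise symmetric MAPEs between rows of a curve matrix;
# optionally a seeded subsample of pairs
pairwise_mape <- function(curves, max_pairs = Inf) {
  n <- nrow(curves)
  if (n < 2L) return(numeric(0))
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  vapply(seq_len(ncol(pairs)), function(j) {
    mape_from_curves(curves[pairs[1, j], ], curves[pairs[2, j], ])
  }, numeric(1))
}

#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalization of the two-sample t-test, used to decide
#' whether parameter vectors fitted at two boot sizes share a mean. The
#' statistic is converted to an F with `(p, n1 + n2 - p - 1)` degrees of
#' freedom. A singular pooled covariance is regularized with a ridge of
#' `1e-8 * trace` on the diagonal.
#'
#' @param x,y Numeric matrices (observations in rows, same number of columns).
#' @return A list with `statistic` (T2), `f`, `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y); p <- ncol(x)
  stopifnot(n1 >= 2, n2 >= 2)
  d <- colMeans(x) - colMeans(y)
  S <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n1 + n2 - 2)
  Si <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Si)) {
    S <- S + diag(1e-8 * sum(diag(S)) + 1e-300, p)
    Si <- solve(S)
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Si %*% d)
  df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  list(statistic = t2, f = f, df1 = p, df2 = df2,
       p_value = stats::pf(f, p, df2, lower.tail = FALSE))
}

#' Smallest boot size with statistically stable parameters
#'
#' Compares the parameter collections of consecutive boot sizes with a
#' two-sample Hotelling T-squared test (a plain two-sample t-test for
#' one-parameter models) and returns the smallest size whose comparison with
#' the next size is non-significant at `alpha` — the size beyond which the
#' estimation does not statistically change. Ties are resolved by the first
#' non-significant consecutive comparison.
#'
#' @param params_by_size Named list (names = boot sizes, increasing order) of
#'   parameter matrices, one fitted vector per row.
#' @param alpha Significance level (default 0.05).
#' @return The stability size (numeric), or `NA` if every comparison is
#'   significant.
#' @export
stability_test <- function(params_by_size, alpha = 0.05) {
  sizes <- as.numeric(names(params_by_size))
  stopifnot(length(sizes) >= 2L)
  for (i in seq_len(length(sizes) - 1L)) {
    a <- as.matrix(params_by_size[[i]])
    b <- as.matrix(params_by_size[[i + 1L]])
    if (nrow(a) < 2L || nrow(b) < 2L) next
    pv <- if (ncol(a) == 1L) {
      tryCatch(stats::t.test(a[, 1], b[, 1])$p.value,
               error = function(e) {
                 # essentially constant data: identical means are stable,
                 # different means are a sure change
                 if (isTRUE(all.equal(mean(a[, 1]), mean(b[, 1])))) 1 else 0
               })
    } else {
      hotelling_t2(a, b)$p_value
    }
    if (!is.na(pv) && pv >= alpha) return(sizes[i])
  }
  NA_real_
}

#' Bootstrap a main-sequence model across boot sizes
#'
#' For each boot size, draws `n_boots` resamples with replacement, fits the
#' model and records the parameter vector, the adjusted R-squared evaluated
#' against the full point set, and all pairwise symmetric curve MAPEs on
#' `grid` (a seeded subsample when pairs exceed `max_pairs`). Resamples on
#' which the model cannot be fitted are recorded as failures and excluded
#' from summaries. Fully deterministic given `seed`.
#'
#' @param points Data frame with `amplitude`, `peak_velocity`.
#' @param model_id One of [mainseq_models].
#' @param boot_sizes Integer vector (default 10 to 100 by 10).
#' @param n_boots Resamples per size (default 1000).
#' @param seed RNG seed.
#' @param constants `fixed_sqrt` constants; computed from `points` when NULL.
#' @param grid Curve-comparison amplitude grid.
#' @param max_pairs Cap on pairwise MAPE evaluations per size.
#' @return An object of class `bootstrap_report`: per-size parameter
#'   matrices, R-squared vectors, MAPE vectors, failure counts, and
#'   `stability_size` from [stability_test()].
#' @export
bootstrap_models <- function(points, model_id, boot_sizes = seq(10, 100, 10),
                             n_boots = 1000, seed = 1, constants = NULL,
                             grid = mainseq_grid(), max_pairs = 1e5) {
  stopifnot(nrow(points) > 0)
  model_id <- match.arg(model_id, mainseq_models)
  if (model_id == "fixed_sqrt" && is.null(constants)) {
    constants <- suppressWarnings(compute_fixed_sqrt_constants(points))
  }
  x <- points$amplitude; y <- points$peak_velocity
  n <- length(x)
  p <- ms_n_params[[model_id]]
  set.seed(seed)
  per_size <- lapply(boot_sizes, function(bs) {
    pars <- matrix(NA_real_, n_boots, p)
    r2 <- numeric(n_boots)
    curves <- matrix(NA_real_, n_boots, length(grid))
    failed <- logical(n_boots)
    for (b in seq_len(n_boots)) {
      idx <- sample.int(n, bs, replace = TRUE)
      res <- tryCatch(ms_fit_params(x[idx], y[idx], model_id, constants),
                      error = function(e) NULL)
      if (is.null(res)) { failed[b] <- TRUE; next }
      pars[b, ] <- res$params
      r2_plain <- ms_r_squared(model_id, res$params, res$constants, x, y)
      r2[b] <- 1 - (1 - r2_plain) * (n - 1) / (n - p - 1)
      curves[b, ] <- ms_predict(model_id, res$params, grid, constants)
    }
    ok <- !failed
    list(params = pars[ok, , drop = FALSE],
         r_squared = r2[ok],
         mape = pairwise_mape(curves[ok, , drop = FALSE], max_pairs),
         n_failed = sum(failed))
  })
  names(per_size) <- boot_sizes
  pbs <- lapply(per_size, `[[`, "params")
  structure(
    list(model_id = model_id, boot_sizes = boot_sizes, n_boots = n_boots,
         constants = constants, grid = grid, seed = seed,
         per_size = per_size,
         stability_size = if (length(boot_sizes) >= 2L)
           stability_test(pbs) else NA_real_),
    class = "bootstrap_report"
  )
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %s, %d boots x sizes {%s}, stability size %s\n",
              x$model_id, x$n_boots,
              paste(x$boot_sizes, collapse = ", "),
              format(x$stability_size)))
  invisible(x)
}

#' @rdname tidy.bootstrap_report
#' @method glance bootstrap_report
#' @export
glance.bootstrap_report <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, n_boots = x$n_boots,
                 stability_size = x$stability_size,
                 n_failed = sum(vapply(x$per_size, `[[`, integer(1), "n_failed")))
}

#' Tidy a bootstrap report
#'
#' One row per boot size with median and quartiles of the adjusted R-squared
#' and of the pairwise MAPE distributions.
#'
#' @param x A `bootstrap_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bootstrap_report
#' @export
tidy.bootstrap_report <- function(x, ...) {
  purrr::imap_dfr(x$per_size, function(s, nm) {
    qr <- unname(stats::quantile(s$r_squared, c(0.25, 0.5, 0.75), na.rm = TRUE))
    qm <- if (length(s$mape))
            unname(stats::quantile(s$mape, c(0.25, 0.5, 0.75)))
          else rep(NA_real_, 3)
    tibble::tibble(model_id = x$model_id, boot_size = as.numeric(nm),
                   r2_q1 = qr[1], r2_median = qr[2], r2_q3 = qr[3],
                   mape_q1 = qm[1], mape_median = qm[2], mape_q3 = qm[3],
                   n_failed = s$n_failed)
  })
}

#' Amplitude-range generalization matrix
#'
#' Fits the model on bootstrap resamples restricted to saccades of amplitude
#' at most each fit range, then evaluates the R-squared against the points
#' within each evaluation range — not just those used for the fit. The entry
#' `(fit_range, eval_range)` is the median R-squared across boots; a row
#' whose fit subset is too small is reported as NA.
#'
#' @param points Data frame with `amplitude`, `peak_velocity`.
#' @param model_id One of [mainseq_models].
#' @param fit_ranges,eval_ranges Amplitude bounds, deg (default 5..25).
#' @param n_boots Bootstrap resamples per fit range.
#' @param seed RNG seed.
#' @param boot_size Resample size; defaults to the fit-subset size.
#' @param constants `fixed_sqrt` constants (computed from `points` when NULL).
#' @return A tibble in long form: `fit_range`, `eval_range`, `r_squared`.
#' @export
range_generalization <- function(points, model_id,
                                 fit_ranges = c(5, 10, 15, 20, 25),
                                 eval_ranges = fit_ranges,
                                 n_boots = 200, seed = 1, boot_size = NULL,
                                 constants = NULL) {
  model_id <- match.arg(model_id, mainseq_models)
  if (model_id == "fixed_sqrt" && is.null(constants)) {
    constants <- suppressWarnings(compute_fixed_sqrt_constants(points))
  }
  set.seed(seed)
  p <- ms_n_params[[model_id]]
  purrr::map_dfr(fit_ranges, function(fr) {
    sub <- points[points$amplitude <= fr, , drop = FALSE]
    if (nrow(sub) < p + 2L) {
      warning("fit range ", fr, " deg has too few points; row skipped",
              call. = FALSE)
      return(tibble::tibble(fit_range = fr, eval_range = eval_ranges,
                            r_squared = NA_real_))
    }
    bs <- if (is.null(boot_size)) nrow(sub) else boot_size
    r2 <- matrix(NA_real_, n_boots, length(eval_ranges))
    for (b in seq_len(n_boots)) {
      idx <- sample.int(nrow(sub), bs, replace = TRUE)
      res <- tryCatch(
        ms_fit_params(sub$amplitude[idx], sub$peak_velocity[idx], model_id,
                      constants),
        error = function(e) NULL)
      if (is.null(res)) next
      for (j in seq_along(eval_ranges)) {
        ev <- points[points$amplitude <= eval_ranges[j], , drop = FALSE]
        r2[b, j] <- ms_r_squared(model_id, res$params, res$constants,
                                 ev$amplitude, ev$peak_velocity)
      }
    }
    tibble::tibble(fit_range = fr, eval_range = eval_ranges,
                   r_squared = apply(r2, 2, stats::median, na.rm = TRUE))
  })
}

#' Cross-condition repeatability (MAPE between two point sets)
#'
#' Test-retest style comparison: for each boot size, `n_boots` bootstrap fits
#' are computed per condition and the symmetric curve MAPE is evaluated
#' between every fit from A and every fit from B (`n_boots^2` pairs, or a
#' seeded subsample of at least `max_pairs` when that product is larger),
#' summarized by median and quartiles.
#'
#' @param points_a,points_b The two conditions' point sets.
#' @param model_id One of [mainseq_models].
#' @param boot_sizes,n_boots,seed,grid,max_pairs As in [bootstrap_models()].
#' @param constants `fixed_sqrt` constants; computed from `points_a` if NULL.
#' @return A tibble: `boot_size`, `mape_q1`, `mape_median`, `mape_q3`,
#'   `n_pairs`, `n_failed`.
#' @export
cross_condition_mape <- function(points_a, points_b, model_id,
                                 boot_sizes = seq(10, 100, 10),
                                 n_boots = 1000, seed = 1,
                                 constants = NULL, grid = mainseq_grid(),
                                 max_pairs = 1e5) {
  stopifnot(nrow(points_a) > 0, nrow(points_b) > 0)
  model_id <- match.arg(model_id, mainseq_models)
  if (model_id == "fixed_sqrt" && is.null(constants)) {
    constants <- suppressWarnings(compute_fixed_sqrt_constants(points_a))
  }
  # common random numbers: both conditions' resamples at a given boot size
  # use the same stream, so identical point sets give identical fits
  boot_curves <- function(pts, bs, stream_seed) {
    set.seed(stream_seed)
    curves <- matrix(NA_real_, n_boots, length(grid))
    for (b in seq_len(n_boots)) {
      idx <- sample.int(nrow(pts), bs, replace = TRUE)
      res <- tryCatch(
        ms_fit_params(pts$amplitude[idx], pts$peak_velocity[idx], model_id,
                      constants),
        error = function(e) NULL)
      if (!is.null(res)) {
        curves[b, ] <- ms_predict(model_id, res$params, grid, constants)
      }
    }
    curves[stats::complete.cases(curves), , drop = FALSE]
  }
  purrr::imap_dfr(boot_sizes, function(bs, i) {
    ca <- boot_curves(points_a, bs, seed + i)
    cb <- boot_curves(points_b, bs, seed + i)
    na <- nrow(ca); nb <- nrow(cb)
    total <- as.double(na) * nb
    set.seed(seed + i)
    if (total > max_pairs) {
      ia <- sample.int(na, max_pairs, replace = TRUE)
      ib <- sample.int(nb, max_pairs, replace = TRUE)
    } else {
      ia <- rep(seq_len(na), times = nb)
      ib <- rep(seq_len(nb), each = na)
    }
    m <- vapply(seq_along(ia), function(k) {
      mape_from_curves(ca[ia[k], ], cb[ib[k], ])
    }, numeric(1))
    q <- unname(stats::quantile(m, c(0.25, 0.5, 0.75)))
    tibble::tibble(boot_size = bs, mape_q1 = q[1], mape_median = q[2],
                   mape_q3 = q[3], n_pairs = length(m),
                   n_failed = 2L * n_boots - na - nb)
  })
}

match_saccades <- function(kin_ref, kin_sub, tol) {
  # greedy nearest-onset matching within tol seconds
  used <- rep(FALSE, nrow(kin_sub))
  idx <- integer(nrow(kin_ref))
  for (i in seq_len(nrow(kin_ref))) {
    d <- abs(kin_sub$onset_time - kin_ref$onset_time[i])
    d[used] <- Inf
    j <- which.min(d)
    idx[i] <- if (length(j) && is.finite(d[j]) && d[j] <= tol) j else NA_integer_
    if (!is.na(idx[i])) used[idx[i]] <- TRUE
  }
  idx
}

#' Robustness of saccade kinematics to downsampling
#'
#' Decimates the trace by each factor, re-runs detection and both kinematic
#' estimators, matches saccades to the original-frequency ones by onset-time
#' proximity, and for every (factor, parameter, method) combination reports a
#' two-sided Wilcoxon rank-sum p-value between original and subsampled
#' estimates together with the squared Pearson correlation of the matched
#' pairs. The matching tolerance defaults to one subsampled sampling period
#' plus one original period, since onsets on the coarse grid are quantized to
#' the coarse period. Unmatched saccades are excluded (count reported).
#'
#' @param trace A [gaze_trace()] at the reference frequency.
#' @param factors Integer decimation factors (default 1:8).
#' @param velocity_threshold,amplitude_threshold Detection and micro-saccade
#'   thresholds.
#' @param endpoint_threshold Threshold for the baseline kinematics, deg/s.
#' @return A tibble: `factor`, `frequency`, `parameter`, `method`, `p_value`,
#'   `r_squared_vs_original`, `n_matched`, `n_unmatched`.
#' @export
subsampling_study <- function(trace, factors = 1:8,
                              velocity_threshold = 20,
                              amplitude_threshold = 1,
                              endpoint_threshold = 50) {
  kin_at <- function(tr) {
    seg <- detect_saccades(tr, velocity_threshold = velocity_threshold)
    if (nrow(seg) == 0L) return(NULL)
    seg <- filter_microsaccades(seg, amplitude_threshold)$kept
    if (nrow(seg) == 0L) return(NULL)
    seg <- project_trajectory(seg, tr)
    saccade_kinematics(seg, tr, method = c("fit", "threshold"),
                       threshold = endpoint_threshold)
  }
  ref <- kin_at(trace)
  if (is.null(ref)) stop("no saccades detected on the reference trace", call. = FALSE)
  fs <- sampling_frequency(trace)
  pars <- c("amplitude", "duration", "peak_velocity")
  purrr::map_dfr(factors, function(f) {
    sub <- if (f == 1L) ref else kin_at(downsample(trace, f))
    freq <- fs / f
    if (is.null(sub)) {
      return(tidyr::expand_grid(factor = f, frequency = freq,
                                parameter = pars,
                                method = c("fit", "threshold"),
                                p_value = NA_real_,
                                r_squared_vs_original = NA_real_,
                                n_matched = 0L, n_unmatched = NA_integer_))
    }
    purrr::map_dfr(c("fit", "threshold"), function(m) {
      a <- ref[ref$method == m, ]
      b <- sub[sub$method == m, ]
      tol <- 1 / freq + 1 / fs
      mi <- match_saccades(a, b, tol)
      ok <- !is.na(mi)
      purrr::map_dfr(pars, function(pp) {
        va <- a[[pp]][ok]; vb <- b[[pp]][mi[ok]]
        fin <- is.finite(va) & is.finite(vb)
        va <- va[fin]; vb <- vb[fin]
        if (length(va) < 3L) {
          return(tibble::tibble(factor = f, frequency = freq, parameter = pp,
                                method = m, p_value = NA_real_,
                                r_squared_vs_original = NA_real_,
                                n_matched = length(va),
                                n_unmatched = sum(!ok)))
        }
        pv <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
        tibble::tibble(factor = f, frequency = freq, parameter = pp,
                       method = m, p_value = pv,
                       r_squared_vs_original = stats::cor(va, vb)^2,
                       n_matched = length(va), n_unmatched = sum(!ok))
      })
    })
  })
}
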