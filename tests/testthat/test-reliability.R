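make_fit <- function(model_id, params, constants = NULL) {
  structure(list(model_id = model_id, params = params, constants = constants),
            class = "mainseq_fit")
}

test_that("symmetric curve MAPE has its closed-form values", {
  fa <- make_fit("sqrt", c(V = 100))
  expect_equal(curve_mape(fa, fa), 0)

  fb <- make_fit("sqrt", c(V = 110)) # y_b = 1.1 y_a everywhere
  expect_equal(curve_mape(fa, fb), 100 * 0.1 / 1.05, tolerance = 1e-9)
  expect_equal(curve_mape(fa, fb), curve_mape(fb, fa))
})

test_that("Hotelling T-squared separates shifted parameter clouds", {
  set.seed(1)
  x <- matrix(rnorm(60), ncol = 2)
  expect_equal(hotelling_t2(x, x)$statistic, 0, tolerance = 1e-12)
  expect_equal(hotelling_t2(x, x)$p_value, 1)

  y <- x + 10 # ten pooled SDs away
  expect_lt(hotelling_t2(x, y)$p_value, 1e-10)

  # singular pooled covariance is regularized, not fatal
  z <- cbind(x[, 1], x[, 1])
  expect_silent(hotelling_t2(z, z + 5))

  # agrees with the univariate t-test squared relationship for p = 1
  a <- matrix(rnorm(30), ncol = 1); b <- matrix(rnorm(30, 0.5), ncol = 1)
  ht <- hotelling_t2(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(ht$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("stability size is the first non-significant consecutive step", {
  set.seed(2)
  base <- matrix(rnorm(100), ncol = 2)
  same <- list("10" = base, "20" = base + rnorm(100, 0, 1e-3))
  expect_equal(stability_test(same), 10)

  shifted <- list("10" = base, "20" = base + 10, "30" = base + 10.001,
                  "40" = base + 20)
  # 10 vs 20 significant, 20 vs 30 not -> 20 (first non-significant wins)
  expect_equal(stability_test(shifted), 20)

  all_diff <- list("10" = base, "20" = base + 10, "30" = base + 20)
  expect_true(is.na(stability_test(all_diff)))
})

test_that("bootstrapping an exact model is degenerate at MAPE 0", {
  pts <- exact_points("sqrt", c(V = 100))
  br <- bootstrap_models(pts, "sqrt", boot_sizes = c(10, 30), n_boots = 40,
                         seed = 1)
  for (s in br$per_size) {
    expect_equal(unname(s$params[, 1]), rep(100, 40), tolerance = 1e-9)
    expect_equal(max(s$mape), 0, tolerance = 1e-9)
    expect_equal(length(s$mape), choose(40, 2))
  }
  expect_equal(br$stability_size, 10)

  # a single boot has no pairs
  b1 <- bootstrap_models(pts, "sqrt", boot_sizes = 20, n_boots = 1, seed = 1)
  expect_length(b1$per_size[[1]]$mape, 0)
})

test_that("bootstrap results are reproducible and improve with boot size", {
  pts <- generate_points(synth_config(n_saccades = 80, relative_noise = 0.15,
                                      seed = 11))
  b1 <- bootstrap_models(pts, "fixed_sqrt", boot_sizes = c(10, 100),
                         n_boots = 120, seed = 9)
  b2 <- bootstrap_models(pts, "fixed_sqrt", boot_sizes = c(10, 100),
                         n_boots = 120, seed = 9)
  expect_identical(b1$per_size[["10"]]$params, b2$per_size[["10"]]$params)
  expect_identical(b1$per_size[["100"]]$mape, b2$per_size[["100"]]$mape)

  expect_lt(median(b1$per_size[["100"]]$mape),
            median(b1$per_size[["10"]]$mape))

  td <- tidy(b1)
  expect_equal(td$boot_size, c(10, 100))
  expect_s3_class(autoplot(b1), "ggplot")
  expect_s3_class(autoplot(b1, "r_squared"), "ggplot")
})

test_that("range generalization: exact data give R-squared 1 everywhere", {
  pts <- exact_points("fixed_sqrt", c(V = 100),
                      constants = list(VA = 40, A_th = 1),
                      amplitudes = seq(1.2, 24.8, length.out = 120))
  rg <- range_generalization(pts, "fixed_sqrt", n_boots = 20, seed = 1,
                             constants = list(VA = 40, A_th = 1))
  expect_true(all(abs(rg$r_squared - 1) < 1e-9))
})

test_that("saturating data expose the slope model's poor generalization", {
  pts <- generate_points(synth_config(n_saccades = 400,
                                      relative_noise = 0.1, seed = 13))
  rg <- range_generalization(pts, "slope", n_boots = 50, seed = 2)
  on_range <- rg$r_squared[rg$fit_range == 5 & rg$eval_range == 5]
  off_range <- rg$r_squared[rg$fit_range == 5 & rg$eval_range == 25]
  expect_gt(on_range, off_range)

  rgf <- range_generalization(pts, "fixed_sqrt", n_boots = 50, seed = 2,
                              constants = list(VA = 40, A_th = 1))
  near <- rgf$r_squared[rgf$fit_range == 5 & rgf$eval_range == 25]
  far <- rgf$r_squared[rgf$fit_range == 25 & rgf$eval_range == 25]
  expect_lt(abs(near - far), 0.05)
})

test_that("cross-condition MAPE reflects a proportional offset", {
  base <- synth_config(n_saccades = 150, relative_noise = 0.1,
                       law = list(model_id = "sqrt", params = c(V = 100)),
                       seed = 31)
  up <- base; up$seed <- 32
  up$law$params <- c(V = 120)
  A <- generate_points(base); B <- generate_points(up)
  cc <- cross_condition_mape(A, B, "sqrt", boot_sizes = 80, n_boots = 120,
                             seed = 6)
  # closed form for curves in ratio 1.2: 100 * 0.2 / 1.1
  expect_equal(cc$mape_median, 100 * 0.2 / 1.1, tolerance = 0.15)

  # identical point sets with one boot each -> a single MAPE of 0
  cc0 <- cross_condition_mape(A, A, "sqrt", boot_sizes = 50, n_boots = 1,
                              seed = 1)
  expect_equal(cc0$n_pairs, 1)
  expect_equal(cc0$mape_median, 0, tolerance = 1e-9)

  # a dataset against itself sits inside the within-condition spread
  br <- bootstrap_models(A, "sqrt", boot_sizes = 80, n_boots = 120, seed = 6)
  cc_self <- cross_condition_mape(A, A, "sqrt", boot_sizes = 80,
                                  n_boots = 120, seed = 7)
  w <- br$per_size[["80"]]$mape
  expect_gt(cc_self$mape_median, quantile(w, 0.25) - 1e-9)
  expect_lt(cc_self$mape_median, quantile(w, 0.75) + 1)
})

test_that("over-parameterized models are less repeatable at boot size 50", {
  pts <- generate_points(synth_config(n_saccades = 100, relative_noise = 0.15,
                                      seed = 11))
  med <- sapply(c("sqrt", "fixed_sqrt", "exponential", "sigmoid"),
                function(m) {
    median(bootstrap_models(pts, m, boot_sizes = 50, n_boots = 120,
                            seed = 3)$per_size[[1]]$mape)
  })
  expect_lt(med[["sqrt"]], med[["exponential"]])
  expect_lt(med[["sqrt"]], med[["sigmoid"]])
  expect_lt(med[["fixed_sqrt"]], med[["exponential"]])
  expect_lt(med[["fixed_sqrt"]], med[["sigmoid"]])
})

test_that("subsampling a trace by factor 1 is a perfect self-comparison", {
  g <- generate_trace(synth_config(n_saccades = 25, noise_sd = 0.05,
                                   seed = 17))
  st <- subsampling_study(g$trace, factors = 1)
  expect_true(all(st$p_value > 0.99, na.rm = TRUE))
  expect_true(all(abs(st$r_squared_vs_original - 1) < 1e-12, na.rm = TRUE))
  expect_equal(unique(st$n_unmatched), 0)
})
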