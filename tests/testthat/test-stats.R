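test_that("RMSE matches direct arithmetic", {
  expect_identical(rmse_curve(rep(1, 96), rep(1, 96)), 0)
  expect_equal(rmse_curve(rep(0.5, 96), rep(0, 96)), 0.5)
  expect_equal(rmse_curve(c(0, 1, 2), c(0, 0, 0)), sqrt(5 / 3),
               tolerance = 1e-12)
  expect_error(rmse_curve(1:3, 1:4), "length mismatch")
  # brute-force oracle on random series
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:96, 1)
    a <- rnorm(n); b <- rnorm(n)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (a[j] - b[j])^2
    expect_lt(abs(rmse_curve(a, b) - sqrt(acc / n)), 1e-12)
  }
})

test_that("RMSE summaries are order statistics per cell", {
  rec <- data.frame(limb_id = c("a", "b", "c"), variant = "ascending",
                    wedge_height_mm = 11, parameter = "patellar_shift",
                    rmse = c(0.4, 0.6, 3.9))
  sm <- summarize_rmse(rec)
  expect_equal(sm$median, 0.6)
  expect_equal(sm$min, 0.4)
  expect_equal(sm$max, 3.9)
  one <- summarize_rmse(rec[1, ])
  expect_true(one$median == one$min && one$min == one$max)
  zero <- rec; zero$rmse <- 0
  expect_true(all(summarize_rmse(zero)[c("median", "min", "max")] == 0))
  expect_error(summarize_rmse(rec[0, ]), "no RMSE records")
})

test_that("paired t-test matches the textbook formula and stats::t.test", {
  tt <- paired_ttest(c(1, 2, 3))
  expect_equal(tt$mean, 2)
  expect_equal(tt$t, 3.464, tolerance = 1e-3)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  expect_identical(tt$df, 2L)
  d0 <- paired_ttest(rep(0, 5))
  expect_true(d0$degenerate)
  expect_true(is.na(d0$p))
  set.seed(43)
  for (i in 1:100) {
    d <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    mine <- paired_ttest(d)
    ref <- stats::t.test(d)
    expect_lt(abs(mine$t - unname(ref$statistic)), 1e-9)
    expect_lt(abs(mine$p - ref$p.value), 1e-9)
  }
})

test_that("change report has the full parameter x variant structure", {
  res <- small_experiment()
  tab <- change_ttest_at_flexion(res, 100, 12)
  expect_identical(nrow(tab), 8L)  # 4 parameters x 2 variants
  expect_setequal(unique(tab$parameter),
                  c("patellar_shift", "patellar_tilt", "patellar_rotation",
                    "tibiofemoral_rotation"))
  expect_setequal(unique(tab$variant), c("ascending", "descending"))
  expect_true(all(tab$df == 1L))
  tab_h <- change_ttest_at_flexion(res, 100, 12, holm = TRUE)
  expect_true("p_holm" %in% names(tab_h))
})

test_that("the mixed model recovers known fixed effects", {
  d <- simulate_mixed_data(n_limbs = 13, slope = 0.3, variant_effect = 0.5,
                           intercept_sd = 1, noise_sd = 0.1, seed = 5)
  fit <- fit_mixed_model_df(d)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "h_c"] - 0.3), 0.05)
  expect_lt(abs(co$estimate[co$term == "variant_asc"] - 0.5), 0.1)
  expect_true(all(co$p >= 0 & co$p <= 1))
  expect_lt(abs(fit$random_intercept_sd - 1), 0.6)
  expect_false(fit$singular)
  expect_true(all(is.finite(fit$standardized)))
})

test_that("mixed models fit at the reporting angles of a small experiment", {
  res <- small_experiment()
  for (a in c(20, 60, 100)) {
    suppressMessages({
      mm <- fit_mixed_model(res, a, "patellar_shift")
    })
    expect_s3_class(mm, "hto_mixed_model")
    expect_identical(mm$n_obs, 8L)
  }
  expect_error(fit_mixed_model(res, 57.5, "patellar_shift"), "no data")
})

test_that("qq export returns matched quantile pairs", {
  res <- small_experiment()
  qq <- qq_export(res, 100)
  expect_setequal(unique(qq$parameter),
                  c("patellar_shift", "patellar_tilt", "patellar_rotation",
                    "tibiofemoral_rotation"))
  for (p in unique(qq$parameter)) {
    s <- qq[qq$parameter == p, ]
    expect_false(is.unsorted(s$sample_quantile))
    expect_false(is.unsorted(s$theoretical_quantile))
  }
})
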