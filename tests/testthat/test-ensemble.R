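test_that("quantile averaging is idempotent, convex and month-checked", {
  m <- as_month("2013-01") + 0:1
  qa <- make_qf(m, rbind(seq(1, 23), seq(2, 24)))
  qb <- make_qf(m, rbind(seq(3, 25), seq(4, 26)))
  same <- combine_quantiles(list(qa, qa, qa))
  expect_equal(same$quantile_values, qa$quantile_values, tolerance = 1e-12)
  ens <- combine_quantiles(list(qa, qb))
  expect_equal(ens$quantile_values, (qa$quantile_values + qb$quantile_values) / 2,
               tolerance = 1e-12)
  expect_true(all(ens$quantile_values >= pmin(qa$quantile_values,
                                              qb$quantile_values)))
  expect_true(all(ens$quantile_values <= pmax(qa$quantile_values,
                                              qb$quantile_values)))
  expect_true(all(apply(ens$quantile_values, 1, diff) >= 0))
  # weighted two-point check: (2,4) and (4,8) at weights 1/2 -> (3,6)
  q1 <- make_qf(m[1], matrix(seq(2, 4, length.out = 23), 1))
  q2 <- make_qf(m[1], matrix(seq(4, 8, length.out = 23), 1))
  w <- combine_quantiles(list(q1, q2))
  expect_equal(unname(w$quantile_values[1, c(1, 23)]), c(3, 6))
  qc <- make_qf(m + 5, rbind(seq(1, 23), seq(2, 24)))
  expect_error(combine_quantiles(list(qa, qc)), "different target months")
  expect_error(combine_quantiles(list(qa, qb), weights = c(0.7, 0.7)),
               "summing to 1")
  expect_error(ensemble_spec(components = "ets"), "at least 2")
})

test_that("ensemble pinball loss never exceeds the worst component", {
  # convexity of the pinball loss in the quantile argument
  set.seed(8)
  for (i in 1:200) {
    m <- as_month("2013-01")
    qa <- make_qf(m, matrix(sort(rnorm(23, 10, 2)), 1))
    qb <- make_qf(m, matrix(sort(rnorm(23, 11, 1)), 1))
    ens <- combine_quantiles(list(qa, qb))
    y <- rnorm(1, 10, 3)
    expect_lte(quantile_score(y, ens),
               max(quantile_score(y, qa), quantile_score(y, qb)) + 1e-9)
  }
})

test_that("exponential smoothing tracks a noiseless linear trend", {
  y <- 1 + 0.01 * (0:59)
  f <- fit_ets(y, seasonal = FALSE)
  qf <- predict_quantiles(f, 60, n_paths = 200, seed = 1)
  expect_equal(unname(qf$point_estimate), 1 + 0.01 * 60, tolerance = 1e-6)
})

test_that("ets captures additive seasonality in its forecasts", {
  t <- 0:71
  y <- 5 + 0.01 * t + 1.5 * sin(2 * pi * t / 12) + rnorm(72, 0, 0.05)
  f <- fit_ets(y, months = t)
  qf <- predict_quantiles(f, 72:77, n_paths = 300, seed = 2)
  truth <- 5 + 0.01 * (72:77) + 1.5 * sin(2 * pi * (72:77) / 12)
  expect_lt(max(abs(qf$point_estimate - truth)), 0.5)
})

test_that("order search returns an admissible in-grid dynamic regression", {
  p <- small_panel()
  sub <- p[p$jurisdiction == "J02" & p$month <= as_month("2011-12"), ]
  f <- fit_arima_search(sub$mortality_rate, sub$month,
                        grid_p = 0:2, grid_q = 0:2)
  expect_s3_class(f, "dynreg_fit")
  expect_identical(f$family, "arima_search")
  expect_true(all(f$order[c(1, 3)] %in% 0:2) && f$order[2] %in% 0:1)
  expect_true(is.finite(f$aicc))
  qf <- predict_quantiles(f, max(sub$month) + 1:6, n_paths = 200, seed = 3)
  expect_true(all(apply(qf$quantile_values, 1, diff) >= 0))
})

test_that("the order search prefers differencing for integrated series", {
  set.seed(14)
  y <- cumsum(rnorm(150, 0.05, 1))
  f <- fit_arima_search(y, grid_p = 0:1, grid_q = 0:1, fourier_K = 1)
  expect_identical(f$order[2], 1L)
})

test_that("neural autoregression validates, fits and simulates", {
  expect_error(fit_nnar(rnorm(100), size = 0), "hidden unit")
  expect_error(fit_nnar(rnorm(20)), "observations")
  t <- 0:95
  y <- 5 + sin(2 * pi * t / 12) + rnorm(96, 0, 0.1)
  f <- fit_nnar(y, months = t, size = 3, seed = 6)
  f2 <- fit_nnar(y, months = t, size = 3, seed = 6)
  expect_identical(serialize(f$net$wts, NULL), serialize(f2$net$wts, NULL))
  qf <- predict_quantiles(f, 96:101, n_paths = 200, seed = 4)
  expect_true(all(is.finite(qf$quantile_values)))
  # in-sample residual scale should be near the innovation scale
  expect_lt(f$sigma, 0.5)
})
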