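test_that("the 23-level set matches the evaluation design", {
  lv <- qf_levels()
  expect_length(lv, 23)
  expect_identical(lv[1:3], c(0.01, 0.025, 0.05))
  expect_identical(rev(lv)[1:3], c(0.99, 0.975, 0.95))
  expect_equal(diff(lv[4:21]), rep(0.05, 17), tolerance = 1e-12)
  expect_equal(lv[which.min(abs(lv - 0.5))], 0.5)
})

test_that("model_spec enforces the family contracts", {
  expect_identical(model_spec("baseline")$fourier_K, 0L)
  expect_identical(model_spec("baseline")$exog_set, character(0))
  expect_identical(model_spec("calls")$exog_set, "log_call_rate")
  expect_length(model_spec("ght")$exog_set, 6)
  expect_length(model_spec("calls_ght")$exog_set, 7)
  expect_error(model_spec("auto", n_paths = 50), "at least 100")
  expect_error(model_spec("nnar", nnar_size = 0), "hidden unit")
})

test_that("baseline drift model reproduces its closed forms", {
  f <- fit_baseline(c(1, 2, 3, 4, 5))
  expect_equal(point_forecast(f, 2), c(6, 7))
  f2 <- fit_baseline(c(4, 4, 4))
  expect_true(f2$degenerate)
  expect_equal(point_forecast(f2, 5), rep(4, 5))
  f3 <- fit_baseline(c(3, 1, 2))
  expect_equal(point_forecast(f3, 1), 1.5)  # drift (2-3)/2 from last value 2
  expect_error(fit_baseline(c(1, 2)), "at least 3")
})

test_that("quantile forecasts are monotone, non-negative, median-exact, seeded", {
  set.seed(1)
  y <- cumsum(rnorm(60, 0.05, 1)) + 20
  f <- fit_baseline(y, months = seq_along(y) - 1L)
  qf <- predict_quantiles(f, length(y) - 1 + 1:6, n_paths = 400, seed = 9)
  expect_s3_class(qf, "quantile_forecast")
  expect_true(all(apply(qf$quantile_values, 1, diff) >= 0))
  expect_true(all(qf$quantile_values >= 0))
  # antithetic innovations make the median the exact analytic point forecast
  expect_equal(unname(qf$point_estimate), point_forecast(f, 6),
               tolerance = 1e-12)
  qf2 <- predict_quantiles(f, length(y) - 1 + 1:6, n_paths = 400, seed = 9)
  expect_identical(qf$quantile_values, qf2$quantile_values)
  qf3 <- predict_quantiles(f, length(y) - 1 + 1:6, n_paths = 400, seed = 10)
  expect_false(identical(qf$quantile_values, qf3$quantile_values))
  expect_error(predict_quantiles(f, length(y) + 1:6, n_paths = 400), "contiguous")
  expect_error(predict_quantiles(f, length(y) - 1 + 1:6, n_paths = 50),
               "at least 100")
})

test_that("degenerate (zero-variance) models collapse to a point mass", {
  f <- fit_baseline(rep(4, 10))
  qf <- predict_quantiles(f, 10:12, n_paths = 200)
  expect_true(all(qf$quantile_values == 4))
})

test_that("simulated quantile spread matches the Gaussian closed form", {
  set.seed(42)
  y <- 100 + cumsum(rnorm(400, 0, 1))
  f <- fit_baseline(y, months = seq_along(y) - 1L)
  qf <- predict_quantiles(f, length(y) - 1 + 1, n_paths = 10000, seed = 3)
  spread <- qf$quantile_values[1, 22] - qf$quantile_values[1, 2] # 0.975 - 0.025
  expect_lt(abs(spread / (2 * qnorm(0.975) * f$sigma) - 1), 0.05)
})

test_that("dynamic harmonic regression recovers a noiseless signal", {
  t <- 0:95
  y <- 2 + 0.01 * t + 0.5 * sin(2 * pi * t / 12) + 0.2 * cos(2 * pi * t / 12)
  f <- fit_auto(y, model_spec("auto", arima_order = c(0, 0, 0), fourier_K = 1),
                months = t)
  qf <- predict_quantiles(f, 96, n_paths = 200, seed = 1)
  truth <- 2 + 0.01 * 96 + 0.5 * sin(2 * pi * 96 / 12) + 0.2 * cos(2 * pi * 96 / 12)
  expect_equal(unname(qf$point_estimate), truth, tolerance = 1e-6)
})

test_that("fit_auto recovers a known generator trend slope within 25%", {
  slopes <- vapply(1:12, function(r) {
    cfg <- generator_config(n_jurisdictions = 1, end_month = "2016-12",
                            trend_slope = 0.004, seasonal_amplitude = 0.05,
                            noise_sd = 0.05, master_seed = 500 + r)
    p <- generate_panel(cfg)      # 120 months
    f <- fit_auto(p$mortality_rate, months = p$month)
    f$beta[f$xreg_names == "drift"]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.004), 0.25 * 0.004)
})

test_that("white-noise series forecast near the series mean", {
  set.seed(7)
  y <- rnorm(120, 10, 1)
  f <- fit_auto(y, model_spec("auto", arima_order = c(1, 0, 0),
                              include_drift = FALSE))
  qf <- predict_quantiles(f, 120:125, n_paths = 400, seed = 2)
  se <- 1 / sqrt(120)
  expect_true(all(abs(qf$point_estimate - mean(y)) < max(2 * se, 0.5)))
})

test_that("uninformative exogenous input reduces augmented fits to auto", {
  p <- small_panel()
  sub <- p[p$jurisdiction == "J01" & p$month <= as_month("2010-12"), ]
  y <- sub$mortality_rate
  spec <- model_spec("calls", n_paths = 200)
  expect_warning(
    f_aug <- fit_augmented(y, matrix(0, length(y), 1,
                                     dimnames = list(NULL, "log_call_rate")),
                           spec, months = sub$month),
    "degenerate|collinear")
  f_auto <- fit_auto(y, model_spec("auto", n_paths = 200), months = sub$month)
  q_aug <- predict_quantiles(f_aug, max(sub$month) + 1:6, n_paths = 200, seed = 5)
  q_auto <- predict_quantiles(f_auto, max(sub$month) + 1:6, n_paths = 200, seed = 5)
  expect_equal(q_aug$quantile_values, q_auto$quantile_values, tolerance = 1e-8)
})

test_that("augmented fits validate exogenous alignment", {
  p <- small_panel()
  sub <- p[p$jurisdiction == "J01" & p$month <= as_month("2010-12"), ]
  y <- sub$mortality_rate
  x <- matrix(log_call_rate(sub$call_rate), ncol = 1,
              dimnames = list(NULL, "log_call_rate"))
  expect_error(fit_augmented(y, x[-1, , drop = FALSE], model_spec("calls")),
               "every training month")
  f <- fit_augmented(y, x, model_spec("calls"), months = sub$month)
  expect_error(predict_quantiles(f, max(sub$month) + 1:3, n_paths = 200),
               "exog_future")
  expect_error(predict_quantiles(f, max(sub$month) + 1:3, n_paths = 200,
                                 exog_future = x[1:2, , drop = FALSE]),
               "one row per target month")
})

test_that("central 95% intervals cover ~95% under correct specification", {
  # fit_auto applied to its own generative family; 600 forecast targets
  set.seed(11)
  hits <- 0L; total <- 0L
  n_train <- 240
  for (r in 1:100) {
    t <- 0:(n_train + 5)
    mu <- 1.2 + 0.002 * t + 0.1 * sin(2 * pi * t / 12)
    e <- as.numeric(arima.sim(list(ar = 0.4, ma = 0.2), n = length(t), sd = 0.1))
    y <- mu + e
    f <- fit_auto(y[1:n_train], model_spec("auto", arima_order = c(1, 0, 1),
                                           fourier_K = 1),
                  months = t[1:n_train])
    qf <- predict_quantiles(f, (n_train - 1) + 1:6, n_paths = 500, seed = r)
    truth <- y[(n_train + 1):(n_train + 6)]
    hits <- hits + sum(truth >= qf$quantile_values[, 2] &
                         truth <= qf$quantile_values[, 22])
    total <- total + 6L
  }
  expect_lt(abs(hits / total - 0.95), 0.03)
})
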