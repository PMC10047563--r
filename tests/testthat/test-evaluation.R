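test_that("MAPE matches hand-computed cases and the zero-truth rule", {
  expect_equal(as.numeric(mape(c(100, 200), c(110, 180))), 0.10)
  expect_equal(as.numeric(mape(c(5, 7, 9), c(5, 7, 9))), 0)
  m <- mape(c(5, 0, 10), c(4, 1, 12))
  expect_equal(as.numeric(m), 0.20)
  expect_identical(attr(m, "n_zero_excluded"), 1L)
  m0 <- mape(c(0, 0), c(1, 2))
  expect_true(is.na(m0))
  expect_true(attr(m0, "undefined"))
  expect_error(mape(1:3, 1:2), "equal")
})

test_that("quantile score is zero iff the truth matches every quantile", {
  q <- matrix(rep(3.2, 23), nrow = 1)
  expect_equal(quantile_score(3.2, q), 0)
  expect_gt(quantile_score(3.3, q), 0)
  # all quantiles at 8, truth 10: sum over levels of 2*alpha*2
  expect_equal(quantile_score(10, matrix(rep(8, 23), nrow = 1)),
               sum(2 * qf_levels() * 2), tolerance = 1e-12)
  expect_error(quantile_score(1, matrix(1, 1, 10)), "23 levels")
})

test_that("vectorized scorer matches the brute-force pinball oracle", {
  set.seed(99)
  for (case in 1:250) {
    q <- sort(rnorm(23, 10, 2))
    y <- rnorm(1, 10, 4)
    expect_equal(quantile_score(y, matrix(q, nrow = 1)), qs_brute(y, q),
                 tolerance = 1e-12)
  }
})

test_that("RQS reproduces closed-form cases and its bounds", {
  expect_equal(as.numeric(rqs(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(rqs(c(0, 0), c(2, 5))), -100)
  expect_equal(as.numeric(rqs(c(1, 1), c(3, 1))), -25)
  set.seed(4)
  for (i in 1:50) {
    a <- rexp(20); r <- rexp(20)
    expect_equal(as.numeric(rqs(a, r)), -as.numeric(rqs(r, a)),
                 tolerance = 1e-12)
    expect_lte(abs(as.numeric(rqs(a, r))), 100)
  }
  v <- rqs(c(0, 1), c(0, 3))
  expect_identical(attr(v, "n_excluded"), 1L)
  expect_error(rqs(c(0, 0), c(0, 0)), "perfect everywhere")
})

test_that("RQS joins score tables on their state-month keys", {
  a <- data.frame(jurisdiction = c("A", "B"), generation_month = "2012-01",
                  qs = c(1, 1))
  r <- data.frame(jurisdiction = c("B", "A"), generation_month = "2012-01",
                  qs = c(1, 3))
  expect_equal(as.numeric(rqs(a, r)), -25)
  r_bad <- r; r_bad$jurisdiction <- c("B", "C")
  expect_error(rqs(a, r_bad), "identical")
})

test_that("Wilcoxon comparison is exact for small n, degenerate when equal", {
  a <- c(1.2, 3.4, 0.8, 2.2, 5.0)
  w <- wilcoxon_compare(a, a + 1)
  expect_equal(w$p_value, 0.0625, tolerance = 1e-12)  # 2 / 2^5
  expect_identical(w$method, "exact")
  wd <- wilcoxon_compare(a, a)
  expect_true(wd$degenerate)
  expect_equal(wd$p_value, 1)
  expect_error(wilcoxon_compare(a[1:4], a[1:4] + 1), "at least 5")
})

test_that("exact enumeration agrees with the reference distribution without ties", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    if (any(a == b) || anyDuplicated(abs(a - b))) next
    ours <- wilcoxon_compare(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("the large-sample approximation holds its nominal size", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    a <- rnorm(40); b <- rnorm(40)
    wilcoxon_compare(a, b)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("calibration coverage matches a correctly specified forecaster", {
  set.seed(21)
  n <- 2000
  mu <- runif(n, 5, 15)
  truths <- rnorm(n, mu, 1.3)
  q <- t(vapply(mu, function(m) qnorm(qf_levels(), m, 1.3), numeric(23)))
  cov <- calibration_curve(q, truths)
  expect_true(all(abs(cov - qf_levels()) < 0.03))
  expect_true(all(diff(as.numeric(cov)) >= 0))
  # total mis-coverage cases
  expect_true(all(calibration_curve(q + 100, truths) == 1))
  expect_true(all(calibration_curve(q - 100, truths) == 0))
  expect_error(calibration_curve(q[1:10, ], truths[1:10]), "at least 30")
})

test_that("Cramer-type distance is zero on the diagonal and consistent", {
  expect_equal(as.numeric(cramers_distance(qf_levels())), 0)
  d <- cramers_distance(qf_levels() + 0.1)
  expect_equal(as.numeric(d), 0.01, tolerance = 1e-12)
  expect_equal(attr(d, "max_abs_deviation"), 0.1, tolerance = 1e-12)
  # distance shrinks toward 0 as the sample grows
  set.seed(31)
  dist_at <- function(n) {
    truths <- rnorm(n)
    q <- matrix(qnorm(qf_levels()), n, 23, byrow = TRUE)
    as.numeric(cramers_distance(calibration_curve(q, truths)))
  }
  d_small <- dist_at(60); d_mid <- dist_at(1000); d_big <- dist_at(10000)
  expect_lt(d_big, d_small)
  expect_lt(d_big, 1e-3)
  expect_lt(d_mid, 5e-3)
})

test_that("stratified summaries partition the score table", {
  sc <- directional_backtest()$scores
  fc <- sc[sc$horizon_kind == "forecast", ]
  overall <- summarize_scores(fc, "overall", reference = "baseline")
  expect_identical(unique(overall$stratum), "all")
  expect_equal(overall$median[overall$family == "auto"],
               median(fc$qs[fc$family == "auto"]))
  by_jur <- summarize_scores(fc, "jurisdiction", reference = "baseline")
  expect_setequal(unique(by_jur$stratum), unique(fc$jurisdiction))
  expect_identical(sum(by_jur$n[by_jur$family == "auto"]),
                   sum(fc$family == "auto"))
  by_year <- summarize_scores(fc, "year")
  expect_setequal(unique(by_year$stratum), c("2012", "2013"))
  one <- summarize_scores(fc[1, , drop = FALSE], "overall")
  expect_equal(one$median, one$mean)
  expect_error(summarize_scores(fc, "decade"), "arg")
  expect_error(summarize_scores(fc, "overall", reference = "nope"),
               "not present")
})
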