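test_that("generated panels form a complete, valid, deterministic grid", {
  cfg <- generator_config(n_jurisdictions = 3, end_month = "2014-12",
                          master_seed = 42)
  p <- small_panel()
  expect_s3_class(p, "surveillance_panel")
  n_months <- as_month("2014-12") - as_month("2007-01") + 1L
  expect_identical(nrow(p), 3L * n_months)
  expect_silent(validate_panel(p))
  expect_true(all(p$mortality_rate >= 0))
  expect_true(all(p$call_rate > 0))
  sr <- as.matrix(p[grep("^search_", names(p))])
  expect_true(all(sr > 0 & sr < 1))
  # byte-identical reproduction after serialization
  p2 <- generate_panel(cfg)
  expect_identical(serialize(p, NULL), serialize(p2, NULL))
  # different seed, different panel
  p3 <- generate_panel(generator_config(n_jurisdictions = 3,
                                        end_month = "2014-12",
                                        master_seed = 43))
  expect_false(identical(p$mortality_rate, p3$mortality_rate))
})

test_that("jurisdiction substreams are stable as the panel widens", {
  cfg2 <- generator_config(n_jurisdictions = 2, end_month = "2010-12",
                           master_seed = 11)
  cfg5 <- generator_config(n_jurisdictions = 5, end_month = "2010-12",
                           master_seed = 11)
  p2 <- generate_panel(cfg2)
  p5 <- generate_panel(cfg5)
  expect_identical(p2$mortality_rate,
                   p5$mortality_rate[p5$jurisdiction %in% c("J01", "J02")])
})

test_that("the copula recovers Spearman targets on flat-mean panels", {
  # ~10k rows, no deterministic structure: pooled Spearman is the copula's
  cfg <- flat_config(5, spearman_with("mortality", "calls", 0.4),
                     seed = 303, end_month = "2023-12")
  p <- generate_panel(cfg)
  expect_gte(nrow(p), 1000)
  sm <- spearman_matrix(p)
  expect_lt(abs(unname(sm$estimate["mortality", "calls"]) - 0.4), 0.05)
  expect_lt(abs(unname(sm$estimate["calls", "mood_anxiety"]) - 0.15), 0.05)
  expect_true(isSymmetric(sm$estimate))
  expect_equal(unname(diag(sm$estimate)), rep(1, 8))
  expect_true(all(sm$estimate >= -1 & sm$estimate <= 1))
})

test_that("study-scale default panel keeps small mortality-proxy correlations", {
  cfg <- generator_config(master_seed = 99)       # 50 x 168 defaults
  p <- generate_panel(cfg)
  expect_identical(nrow(p), 8400L)
  sm <- spearman_matrix(p)
  # 0.10 target, attenuated by trend/seasonal structure but inside +-0.05
  expect_lt(abs(unname(sm$estimate["mortality", "calls"]) - 0.10), 0.05)
  # strong cross-proxy structure survives the marginal transforms
  expect_lt(abs(unname(sm$estimate["calls", "mood_anxiety"]) - 0.40), 0.05)
  expect_lt(max(sm$p_value["mortality", -1]), 0.05)
})

test_that("seasonal signal dominates the periodogram at period 12", {
  cfg <- generator_config(n_jurisdictions = 1, end_month = "2016-12",
                          trend_slope = 0, seasonal_amplitude = 0.4,
                          noise_sd = 0.1, master_seed = 5)
  p <- generate_panel(cfg)
  spec <- stats::spec.pgram(p$mortality_rate, plot = FALSE, detrend = TRUE)
  peak_freq <- spec$freq[which.max(spec$spec)]
  expect_equal(1 / peak_freq, 12, tolerance = 0.1)
})

test_that("infeasible correlation targets fail naming the offending pair", {
  bad <- default_spearman_targets()
  bad["mortality", "calls"] <- bad["calls", "mortality"] <- 0.95
  bad["mortality", "suicide_seeking"] <- bad["suicide_seeking", "mortality"] <- 0.95
  bad["calls", "suicide_seeking"] <- bad["suicide_seeking", "calls"] <- -0.95
  expect_error(generate_panel(flat_config(1, bad)),
               "not positive definite.*(mortality|calls|suicide_seeking)")
  expect_error(generator_config(spearman_targets = diag(8) + 1),
               "unit diagonal|in \\(-1, 1\\)")
})

test_that("spearman_matrix flags undefined pairs and tiny inputs", {
  p <- small_panel()[1:50, ]
  p$mortality_rate <- 1.0   # constant column
  sm <- spearman_matrix(p)
  expect_true(sm$undefined["mortality", "calls"])
  expect_true(is.na(sm$estimate["mortality", "calls"]))
  expect_false(sm$undefined["calls", "mood_anxiety"])
  expect_error(spearman_matrix(small_panel()[1:2, ]), "at least 3")
})

test_that("count mode realizes rates on the count lattice", {
  cfg <- generator_config(n_jurisdictions = 2, end_month = "2008-12",
                          populations = c(1e6, 2e6), count_mode = TRUE,
                          master_seed = 8)
  p <- generate_panel(cfg)
  r1 <- p$mortality_rate[p$jurisdiction == "J01"]
  # rates are integer deaths / 1e6 * 1e5: multiples of 0.1
  expect_equal(r1 * 10, round(r1 * 10), tolerance = 1e-9)
})

test_that("panel CSV round-trips through ISO month labels", {
  p <- small_panel()
  tmp <- tempfile(fileext = ".csv")
  write_panel(p, tmp)
  hdr <- readLines(tmp, n = 2)
  expect_match(hdr[2], "J01,2007-01")
  p2 <- read_panel(tmp)
  expect_equal(p2$mortality_rate, p$mortality_rate, tolerance = 1e-12)
  expect_identical(p2$month, p$month)
})
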