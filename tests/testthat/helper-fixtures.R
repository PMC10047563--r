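# Shared fixtures, built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small default-structure panel: 3 jurisdictions, 2007-2014
small_panel <- function() {
  cached("small_panel", function() {
    generate_panel(generator_config(n_jurisdictions = 3,
                                    end_month = "2014-12",
                                    master_seed = 42))
  })
}

# flat-mean config isolates the copula: no trend, no seasonality
flat_config <- function(n_jur, targets = default_spearman_targets(),
                        seed = 7, end_month = "2020-12") {
  generator_config(n_jurisdictions = n_jur, end_month = end_month,
                   trend_slope = 0, seasonal_amplitude = 0,
                   spearman_targets = targets, master_seed = seed)
}

spearman_with <- function(a, b, rho, base = 0.15, mort = 0.10) {
  m <- matrix(base, 8, 8, dimnames = dimnames(default_spearman_targets()))
  m["mortality", ] <- m[, "mortality"] <- mort
  diag(m) <- 1
  m[a, b] <- m[b, a] <- rho
  m
}

make_qf <- function(target_months, values, horizon_kind = "forecast") {
  lagcast:::new_quantile_forecast(as_month(target_months),
                                  as.matrix(values), horizon_kind)
}

# term-by-term transliteration of the printed pinball formula, kept naive
# on purpose as the oracle for the vectorized scorer
qs_brute <- function(y, q, levels = qf_levels()) {
  total <- 0
  for (i in seq_along(levels)) {
    a <- levels[i]
    if (y >= q[i]) total <- total + 2 * a * (y - q[i])
    else total <- total + 2 * (1 - a) * (q[i] - y)
  }
  total
}

# The synthetic study-condition backtest behind the directional and
# leak-audit checks: 5 jurisdictions, 24 monthly cycles (2012-2013), all
# proxies generated at Spearman 0.4 to mortality, all five core families.
directional_backtest <- function() {
  cached("directional_backtest", function() {
    targets <- matrix(0.30, 8, 8,
                      dimnames = dimnames(default_spearman_targets()))
    targets["mortality", ] <- targets[, "mortality"] <- 0.40
    diag(targets) <- 1
    cfg <- generator_config(n_jurisdictions = 5, end_month = "2014-12",
                            base_rate = 1.1, trend_slope = 0.003,
                            seasonal_amplitude = 0.08, noise_sd = 0.12,
                            spearman_targets = targets,
                            master_seed = 20120101)
    panel <- generate_panel(cfg)
    families <- c("baseline", "auto", "calls", "ght", "calls_ght")
    specs <- stats::setNames(
      lapply(families, function(f) model_spec(f, n_paths = 500)), families)
    run <- run_rolling(panel, as_month("2012-01"):as_month("2013-12"),
                       families, specs = specs, master_seed = 99)
    list(panel = panel, run = run,
         scores = score_backtest(run, panel))
  })
}
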