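#!/usr/bin/env Rscript
# Step 5 — multi-model ensemble by quantile averaging.
#
# Runs the two alternative forecasters (additive exponential smoothing and
# the order-searching ARIMA) alongside the fixed-order auto model on two
# jurisdictions over the 2012 validation cycles, forms the Vincentized
# ensemble of the two alternatives, and compares forecast quantile scores.
# The ensemble can never score worse than its worst component on any
# cycle (pinball convexity); its scores sit inside the component envelope.
#
# Reads:  scratch/panel.csv
# Writes: results/ensemble_scores.csv

suppressPackageStartupMessages(library(lagcast))

panel <- read_panel("scratch/panel.csv")
panel2 <- panel[panel$jurisdiction %in% c("J01", "J02"), ]
fams <- c("auto", "ets", "arima_search")
specs <- setNames(lapply(fams, function(f) model_spec(f, n_paths = 300)), fams)
cycles <- as_month("2012-01"):as_month("2012-12")
run <- run_rolling(panel2, cycles, fams, specs = specs, master_seed = 11L)
stopifnot(nrow(run$failures) == 0, nrow(audit_leaks(run)) == 0)
ens <- combine_run(run, ensemble_spec(components = c("ets", "arima_search")))
run$results <- c(run$results, ens$results)

sc <- score_backtest(run, panel2, horizon_kind = "forecast")
write.csv(sc, "results/ensemble_scores.csv", row.names = FALSE)
med <- sort(tapply(sc$qs, sc$family, median))
cat("forecast quantile score, median by family (2 jurisdictions, 2012):\n")
print(round(med, 3))

comp <- sc[sc$family %in% c("ets", "arima_search"), ]
worst <- tapply(comp$qs, paste(comp$jurisdiction, comp$generation_month), max)
e <- sc[sc$family == "ensemble", ]
e_qs <- e$qs[match(names(worst), paste(e$jurisdiction, e$generation_month))]
cat(sprintf("\nensemble <= worst component on %d / %d cycles (expected: all)\n",
            sum(e_qs <= worst + 1e-9), length(worst)))
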