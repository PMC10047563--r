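#!/usr/bin/env Rscript
# Step 2 — rolling hindcast-then-forecast backtest.
#
# Takes the panel from step 1, restricts to five jurisdictions (models are
# trained independently per jurisdiction, so a subset exercises everything
# at a fraction of the cost), and runs the rolling monthly cycles:
# validation 2012-01 .. 2013-12 and a held-out test year 2014, for the
# five core families (baseline, auto, calls, ght, calls_ght). Each cycle
# hindcasts the 12-23 month release gap, stitches the medians onto the
# observations, and issues 6-month-ahead 23-level quantile forecasts.
#
# Reads:  scratch/panel.csv            (run 01_simulate.R first)
# Writes: results/scores.csv, results/leak_audit.txt,
#         scratch/backtest/quantiles_<period>.csv (bulky, regenerable)

suppressPackageStartupMessages(library(lagcast))
dir.create("scratch/backtest", showWarnings = FALSE, recursive = TRUE)

panel <- read_panel("scratch/panel.csv")
jur <- sprintf("J%02d", 1:5)
panel5 <- panel[panel$jurisdiction %in% jur, ]
families <- c("baseline", "auto", "calls", "ght", "calls_ght")
specs <- setNames(lapply(families, function(f) model_spec(f, n_paths = 500)),
                  families)

scores <- list()
for (period in c("validation", "test")) {
  cycles <- if (period == "validation")
    as_month("2012-01"):as_month("2013-12") else
    as_month("2014-01"):as_month("2014-12")
  t0 <- Sys.time()
  run <- run_rolling(panel5, cycles, families, specs = specs,
                     master_seed = if (period == "validation") 1L else 2L)
  cat(sprintf("%s: %d cycle results, %d skipped (%.1f s)\n", period,
              length(run$results), nrow(run$failures),
              as.numeric(Sys.time() - t0, units = "secs")))
  audit <- audit_leaks(run)
  stopifnot(nrow(audit) == 0)
  write.csv(as_quantile_df(run),
            sprintf("scratch/backtest/quantiles_%s.csv", period),
            row.names = FALSE)
  st <- score_backtest(run, panel5)
  st$period <- period
  scores[[period]] <- st
}
all_scores <- do.call(rbind, unname(scores))
write.csv(all_scores, "results/scores.csv", row.names = FALSE)
writeLines(c("leak audit: clean",
             sprintf("cycles audited: %d", nrow(all_scores) / 2)),
           "results/leak_audit.txt")

fc <- all_scores[all_scores$horizon_kind == "forecast" &
                   all_scores$period == "validation", ]
cat("\nvalidation-period forecast quantile score, median by family:\n")
print(round(sort(tapply(fc$qs, fc$family, median)), 3))
cat("\n(lower is better; trend/season-aware families should clearly\n")
cat("undercut the baseline persistence model. With the default panel's\n")
cat("small mortality-proxy correlations (~0.1) the augmented families\n")
cat("track auto closely; their advantage grows with proxy informativeness\n")
cat("- the property suite demonstrates it at rank correlation 0.4.)\n")
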