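#!/usr/bin/env Rscript
# Step 1 — simulate the study-scale surveillance panel.
#
# Builds the full 50-jurisdiction x 168-month (2007-01 .. 2020-12) monthly
# panel of mortality rates, crisis-call rates and six search-proportion
# streams, and summarises its pooled rank-correlation structure. The
# mortality-proxy correlations are small and positive by design; the
# strongest dependencies sit between the call stream and the
# mood/anxiety and suicide-prevention search categories.
#
# Writes: scratch/panel.csv (bulky, regenerable),
#         results/spearman_estimates.csv

suppressPackageStartupMessages(library(lagcast))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- generator_config(master_seed = 20070101)
panel <- generate_panel(cfg)
cat(sprintf("generated panel: %d rows (%d jurisdictions x %d months)\n",
            nrow(panel), length(unique(panel$jurisdiction)),
            length(unique(panel$month))))
write_panel(panel, "scratch/panel.csv")

sm <- spearman_matrix(panel)
est <- as.data.frame(as.table(sm$estimate))
names(est) <- c("stream_a", "stream_b", "spearman")
est$p_value <- as.data.frame(as.table(sm$p_value))$Freq
write.csv(est, "results/spearman_estimates.csv", row.names = FALSE)

cat("\npooled Spearman estimates (selected pairs):\n")
for (pair in list(c("mortality", "calls"),
                  c("mortality", "mood_anxiety"),
                  c("calls", "mood_anxiety"),
                  c("calls", "suicide_prevention"),
                  c("mood_anxiety", "suicide_prevention"))) {
  cat(sprintf("  %-12s ~ %-20s rho = %+.3f  (p = %.2g)\n",
              pair[1], pair[2],
              sm$estimate[pair[1], pair[2]], sm$p_value[pair[1], pair[2]]))
}
cat("\nNote: mortality-proxy estimates sit slightly below their copula\n")
cat("targets because the deterministic trend/seasonal structure of the\n")
cat("mortality series dilutes pooled rank correlations.\n")
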