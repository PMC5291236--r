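#!/usr/bin/env Rscript
# Stage 2: EPSC sweep analysis.
#
# Reads every simulated experiment back from CSV, detects successes and
# failures, averages success sweeps, fits the single-exponential decay of
# the averaged NMDA EPSC and forms the NMDA:AMPA ratio per experiment, then
# compares the two groups on within-animal averages (unpaired t on decay
# tau; Mann-Whitney on the ratio, which is not normally distributed).

suppressPackageStartupMessages(library(barreldev))
sim_dir <- "results/sim"
stopifnot(dir.exists(sim_dir))

m70 <- sort(list.files(sim_dir, pattern = "_m70\\.csv$", full.names = TRUE))
rows <- lapply(m70, function(f) {
  ss70 <- read_sweep_csv(f)
  ss40 <- read_sweep_csv(sub("_m70", "_p40", f))
  row <- analyze_experiment(ss70, ss40)
  row$experiment_id <- ss70$experiment_id
  row$animal_id <- sub("_exp", "_animal", ss70$experiment_id)
  row$group <- sub("_.*", "", row$experiment_id)
  row
})
per_exp <- do.call(rbind, rows)
utils::write.csv(per_exp, "results/epsc_per_experiment.csv", row.names = FALSE)

by_group <- split(per_exp, per_exp$group)
tau_test <- t_raw(by_group$wt$nmda_tau_ms, by_group$ko$nmda_tau_ms)
ratio_test <- mann_whitney_u(by_group$wt$nmda_ampa_ratio,
                             by_group$ko$nmda_ampa_ratio)

summary_tab <- do.call(rbind, lapply(names(by_group), function(g) {
  d <- by_group[[g]]
  data.frame(group = g, n = nrow(d),
             failure_rate = mean(d$failure_rate),
             mean_amp_pA = mean(abs(d$mean_amp_pA)),
             nmda_tau_ms = mean(d$nmda_tau_ms),
             nmda_ampa_ratio = mean(d$nmda_ampa_ratio))
}))
utils::write.csv(summary_tab, "results/epsc_group_summary.csv", row.names = FALSE)

message("per-group means:")
print(summary_tab, digits = 3)
message(sprintf(
  "NMDA decay tau, wt vs ko (Welch t on per-experiment values): t = %.2f, p = %.3g",
  tau_test$t, tau_test$p_two_tailed))
message(sprintf(
  "NMDA:AMPA ratio, wt vs ko (Mann-Whitney): U = %.1f, p = %.3g (%s)",
  ratio_test$u_statistic, ratio_test$p_two_tailed, ratio_test$method))
message("wrote results/epsc_per_experiment.csv, results/epsc_group_summary.csv")
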