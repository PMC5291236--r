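#!/usr/bin/env Rscript
# Stage 5: group statistics from published summary triplets.
#
# Recomputes the unpaired t-tests from the published (mean, SEM, N)
# summaries. These inputs are rounded to their printed precision, so the
# recomputed p-values agree with the published ones to that precision only.

suppressPackageStartupMessages(library(barreldev))

comparisons <- list(
  brain_mass_mg = list(g1 = group_summary(274, 5, 16),
                       g2 = group_summary(241, 5, 12), variant = "welch"),
  neocortex_mm2 = list(g1 = group_summary(28.4, 0.7, 16),
                       g2 = group_summary(25.0, 0.9, 10), variant = "pooled"),
  pmbsf_mm2 = list(g1 = group_summary(1.21, 0.03, 16),
                   g2 = group_summary(1.09, 0.03, 12), variant = "welch"),
  patch_area_mm2 = list(g1 = group_summary(0.165, 0.007, 16),
                        g2 = group_summary(0.134, 0.003, 12), variant = "welch"),
  segregation_ratio = list(g1 = group_summary(1.6, 0.1, 5),
                           g2 = group_summary(1.8, 0.2, 6), variant = "welch")
)

tab <- do.call(rbind, lapply(names(comparisons), function(nm) {
  cc <- comparisons[[nm]]
  r <- t_from_summary(cc$g1, cc$g2, cc$variant)
  data.frame(comparison = nm, variant = r$variant,
             t = r$t, df = r$df, p_two_tailed = r$p_two_tailed)
}))
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/summary_stats.csv", row.names = FALSE)
print(tab, digits = 3)

# paired design example: ifenprodil inhibition arithmetic
message(sprintf("ifenprodil example: control 100 pA, drug 34 pA -> %.0f%% inhibition",
                ifenprodil_inhibition(100, 34)))
message("wrote results/summary_stats.csv")
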