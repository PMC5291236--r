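#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Two cohorts are simulated at the published operating points: a wild-type-
# like group (NMDA decay tau 71 ms, NMDA:AMPA 0.84, ~50% of paired
# recordings sharing an axon, wall:hollow density ratio 1.6, crossing
# intensities 12.4/9.8 per ROI) and a knockout-like group (tau 43 ms, shared
# proportion ~19%, ratio 1.8, intensities 7.1/6.3). Everything downstream
# reads only the CSVs written here.

suppressPackageStartupMessages(library(barreldev))
seed <- 20260101L
sim_dir <- "results/sim"
dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)

groups <- list(
  wt = list(nmda_tau = 71, nmda_ampa = 0.84, n_pairs = 9, prop_shared = 5 / 9,
            rho_wall = 0.032, lambda_centre = 12.4, lambda_septa = 9.8),
  ko = list(nmda_tau = 43, nmda_ampa = 0.83, n_pairs = 21, prop_shared = 4 / 21,
            rho_wall = 0.036, lambda_centre = 7.1, lambda_septa = 6.3)
)

message("simulating minimal-stimulation EPSC experiments (28 trials, failure rate 0.48) ...")
n_experiments <- 6
gi <- 0L
for (g in names(groups)) {
  gi <- gi + 1L
  gp <- groups[[g]]
  for (i in seq_len(n_experiments)) {
    base_seed <- seed + 1000L * gi + 10L * i
    ids <- list(experiment_id = sprintf("%s_exp%02d", g, i),
                animal_id = sprintf("%s_animal%02d", g, i))
    ss70 <- gen_epsc_sweeps(epsc_gen_config(
      holding_mV = -70, ampa_amp_pA = 40, nmda_amp_pA = gp$nmda_ampa * 40,
      nmda_decay_ms = gp$nmda_tau, seed = base_seed,
      experiment_id = ids$experiment_id, animal_id = ids$animal_id))
    ss40 <- gen_epsc_sweeps(epsc_gen_config(
      holding_mV = 40, ampa_amp_pA = 0, nmda_amp_pA = gp$nmda_ampa * 40,
      nmda_decay_ms = gp$nmda_tau, seed = base_seed + 1L,
      experiment_id = ids$experiment_id, animal_id = ids$animal_id))
    write_sweep_csv(ss70, file.path(sim_dir, sprintf("%s_m70.csv", ids$experiment_id)),
                    params = list(seed = base_seed, holding_mV = -70))
    write_sweep_csv(ss40, file.path(sim_dir, sprintf("%s_p40.csv", ids$experiment_id)),
                    params = list(seed = base_seed + 1L, holding_mV = 40))
  }
}

message("simulating paired recordings (shared vs independent axon topologies) ...")
gi <- 0L
for (g in names(groups)) {
  gi <- gi + 1L
  gp <- groups[[g]]
  n_shared <- round(gp$prop_shared * gp$n_pairs)
  for (i in seq_len(gp$n_pairs)) {
    oc <- gen_dual_cell(dual_cell_gen_config(
      n_trials = 28, shared = i <= n_shared, p_release = 0.52,
      detect_a = 1, detect_b = 0.92, p_a = 0.52, p_b = 0.52,
      seed = seed + 20000L * gi + 7L * i,
      experiment_id = sprintf("%s_pair%02d", g, i)))
    write_trials_csv(oc, file.path(sim_dir, sprintf("%s_pair%02d.csv", g, i)))
  }
}

message("simulating barrel nuclei stacks and axon fields ...")
gi <- 0L
for (g in names(groups)) {
  gi <- gi + 1L
  gp <- groups[[g]]
  field <- gen_barrel_points(barrel_gen_config(
    r_hollow = 100, r_wall = 150, rho_hollow = 0.02, rho_wall = gp$rho_wall,
    rho_outside = 0.02, n_sections = 5, seed = seed + 300L * gi))
  write_points_csv(field, file.path(sim_dir, sprintf("%s_nuclei.csv", g)))
  rois <- lapply(1:3, function(i) roi_rect(center_xy = c(400 * i, 0)))
  rois_s <- lapply(1:3, function(i) roi_rect(center_xy = c(400 * i, 300),
                                             angle_deg = 90))
  segs <- do.call(rbind, c(
    lapply(seq_along(rois), function(i) gen_axon_segments(
      axon_field_config(lambda_centre = gp$lambda_centre,
                        lambda_septa = gp$lambda_septa,
                        seed = seed + 300L * gi + 11L * i),
      rois[[i]], "centre")),
    lapply(seq_along(rois_s), function(i) gen_axon_segments(
      axon_field_config(lambda_centre = gp$lambda_centre,
                        lambda_septa = gp$lambda_septa,
                        seed = seed + 300L * gi + 11L * i + 5L),
      rois_s[[i]], "septa"))))
  write_segments_csv(segs, file.path(sim_dir, sprintf("%s_axons.csv", g)))
}

message(sprintf("done: %d files under %s",
                length(list.files(sim_dir)), sim_dir))
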