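# Synthetic-data generators: construction guarantees, reproducibility and
# convergence of empirical rates to configured parameters.

test_that("EPSC generation is reproducible and respects amplitude semantics", {
  cfg <- quick_epsc_config(seed = 11)
  a <- gen_epsc_sweeps(cfg)
  b <- gen_epsc_sweeps(cfg)
  expect_identical(a$currents, b$currents)
  expect_identical(a$truth, b$truth)

  # noiseless, failure-free sweeps peak exactly at the configured amplitude
  # and at the same (analytic) latency on every sweep
  cfg0 <- quick_epsc_config(noise_sd_pA = 0, p_failure = 0, amp_cv = 0,
                            ampa_amp_pA = 50, nmda_amp_pA = 0,
                            n_sweeps = 6, seed = 1)
  ss <- gen_epsc_sweeps(cfg0)
  calls <- detect_events(ss)
  expect_true(all(abs(calls$peak_amp_pA - (-50)) <= 0.5))
  expect_equal(length(unique(calls$peak_time_ms)), 1L)
  expect_true(all(calls$peak_time_ms > 0))

  # at +40 mV the EPSC is outward
  ss40 <- gen_epsc_sweeps(quick_epsc_config(holding_mV = 40, noise_sd_pA = 0,
                                            p_failure = 0, amp_cv = 0,
                                            n_sweeps = 3, seed = 1))
  expect_gt(max(ss40$currents), 0)
  expect_gte(min(ss40$currents), -1e-12)
})

test_that("degenerate failure probabilities behave as constructed", {
  ss_all_fail <- gen_epsc_sweeps(quick_epsc_config(p_failure = 1, seed = 2,
                                                   n_sweeps = 20))
  expect_true(all(ss_all_fail$truth$is_failure))
  calls <- detect_events(ss_all_fail)
  expect_true(mean(calls$is_success) <= 0.05)  # noise-only false positives only

  ss_none <- gen_epsc_sweeps(quick_epsc_config(p_failure = 0, seed = 3,
                                               n_sweeps = 20))
  expect_false(any(ss_none$truth$is_failure))
})

test_that("failure fraction converges to the configured rate", {
  # ~0.48 failures per trial; Monte-Carlo check against the binomial SE
  n <- 6000L
  ss <- gen_epsc_sweeps(quick_epsc_config(p_failure = 0.48, n_sweeps = n,
                                          seed = 5))
  frac <- mean(ss$truth$is_failure)
  se <- sqrt(0.48 * 0.52 / n)
  expect_lt(abs(frac - 0.48), 3 * se)
})

test_that("invalid EPSC configs fail naming the offending field", {
  expect_error(epsc_gen_config(dt_ms = 0), class = "barreldev_config_error")
  expect_error(epsc_gen_config(p_failure = 1.4), "p_failure")
  expect_error(epsc_gen_config(ampa_decay_ms = 0.2, ampa_rise_ms = 0.5),
               "ampa_decay_ms")
  expect_error(epsc_gen_config(holding_mV = 0), "holding_mV")
  expect_error(epsc_gen_config(n_sweeps = 0), "n_sweeps")
})

test_that("dual-cell outcomes follow the configured topology", {
  # perfect detection in shared mode: identical outcome vectors
  oc <- gen_dual_cell(dual_cell_gen_config(shared = TRUE, detect_a = 1,
                                           detect_b = 1, p_release = 0.5,
                                           n_trials = 200, seed = 8))
  expect_identical(oc$success_a, oc$success_b)

  # independent mode with p_b = 0: cell B never responds
  oc2 <- gen_dual_cell(dual_cell_gen_config(shared = FALSE, p_a = 0.5,
                                            p_b = 0, n_trials = 100, seed = 9))
  expect_false(any(oc2$success_b))
  expect_identical(sum(oc2$success_a & oc2$success_b), 0L)

  # reproducibility
  cfg <- dual_cell_gen_config(seed = 10)
  expect_identical(gen_dual_cell(cfg), gen_dual_cell(cfg))

  expect_error(dual_cell_gen_config(p_release = -0.1),
               class = "barreldev_config_error")
})

test_that("shared-mode coincidence and marginals converge to theory", {
  n <- 1e5L
  oc <- gen_dual_cell(dual_cell_gen_config(shared = TRUE, p_release = 0.52,
                                           detect_a = 1, detect_b = 0.92,
                                           n_trials = n, seed = 12))
  # conditional coincidence: fraction of A-successes with a B-success
  frac <- sum(oc$success_a & oc$success_b) / sum(oc$success_a)
  se <- sqrt(0.92 * 0.08 / sum(oc$success_a))
  expect_lt(abs(frac - 0.92), 4 * se)
  # marginal success rate of cell i = p_release * detect_i
  expect_lt(abs(mean(oc$success_a) - 0.52), 4 * sqrt(0.52 * 0.48 / n))
  expect_lt(abs(mean(oc$success_b) - 0.52 * 0.92),
            4 * sqrt(0.4784 * 0.5216 / n))
})

test_that("barrel point fields realise the configured densities", {
  # equal densities -> downstream ratio ~ 1; doubled wall density -> ~2
  base <- list(r_hollow = 100, r_wall = 150, n_sections = 3)
  geom <- barrel_annulus(r_hollow = 100, r_wall = 150)
  f_eq <- gen_barrel_points(barrel_gen_config(
    r_hollow = 100, r_wall = 150, rho_hollow = 0.2, rho_wall = 0.2,
    rho_outside = 0.05, n_sections = 3, seed = 13))
  expect_gt(nrow(f_eq$points), 1e4)
  per <- segregation_ratio(f_eq, geom)$per_section$ratio
  expect_true(all(abs(per - 1) < 0.05))

  f_2x <- gen_barrel_points(barrel_gen_config(
    r_hollow = 100, r_wall = 150, rho_hollow = 0.2, rho_wall = 0.4,
    rho_outside = 0.05, n_sections = 3, seed = 14))
  per2 <- segregation_ratio(f_2x, geom)$per_section$ratio
  expect_true(all(abs(per2 - 2) < 0.1))

  # empty field propagates as an insufficient-data error downstream
  f0 <- gen_barrel_points(barrel_gen_config(rho_hollow = 0, rho_wall = 0,
                                            rho_outside = 0, seed = 15))
  expect_error(segregation_ratio(f0, geom),
               class = "barreldev_insufficient_data_error")

  expect_error(barrel_gen_config(r_hollow = 150, r_wall = 100),
               class = "barreldev_config_error")
  cfg <- barrel_gen_config(seed = 16)
  expect_identical(gen_barrel_points(cfg), gen_barrel_points(cfg))
})

test_that("axon segment generation matches its Poisson law", {
  roi <- roi_rect(center_xy = c(50, -20), angle_deg = 25)
  s0 <- gen_axon_segments(axon_field_config(lambda_centre = 0, seed = 17),
                          roi, "centre")
  expect_identical(nrow(s0), 0L)
  expect_identical(count_crossings(s0, roi), 0L)

  # every generated traversing segment crosses the ROI; distractors never do
  s <- gen_axon_segments(axon_field_config(lambda_centre = 15,
                                           n_distractors = 5, seed = 18),
                         roi, "centre")
  expect_identical(count_crossings(s, roi), sum(s$traversing))
  expect_identical(count_crossings(s[!s$traversing, ], roi), 0L)

  # mean traversing count converges to lambda
  counts <- vapply(1:400, function(i)
    nrow(gen_axon_segments(axon_field_config(lambda_centre = 10, seed = 100 + i),
                           roi, "centre")), numeric(1))
  expect_lt(abs(mean(counts) - 10), 4 * sqrt(10 / 400))
})
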