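# Event detection, QC, averaging and decay fitting.

test_that("detect_event handles flat, clean and noisy traces correctly", {
  t <- seq(-5, 25, by = 0.1)
  flat <- list(time_ms = t, current_pA = rep(0, length(t)))
  call <- detect_event(flat)
  expect_false(call$is_success)
  expect_identical(call$peak_amp_pA, 0)

  # noiseless EPSC with -50 pA extremum against a 5 pA floor
  ss <- gen_epsc_sweeps(quick_epsc_config(noise_sd_pA = 0, p_failure = 0,
                                          amp_cv = 0, ampa_amp_pA = 50,
                                          nmda_amp_pA = 0, n_sweeps = 1,
                                          seed = 1))
  call <- detect_event(get_sweep(ss, 1), floor_pA = 5)
  expect_true(call$is_success)
  expect_equal(call$peak_amp_pA, -50, tolerance = 0.01)

  # detection power: -30 pA against 2 pA noise at k_sd = 3 is near-certain
  ss <- gen_epsc_sweeps(quick_epsc_config(noise_sd_pA = 2, p_failure = 0,
                                          amp_cv = 0, ampa_amp_pA = 30,
                                          nmda_amp_pA = 0, n_sweeps = 1000,
                                          seed = 2))
  calls <- detect_events(ss, k_sd = 3, floor_pA = 5)
  expect_gte(mean(calls$is_success), 0.99)

  expect_error(detect_event(flat, response_window_ms = c(1, 500)),
               class = "barreldev_bounds_error")
})

test_that("false-positive rate on pure noise matches a simulation oracle", {
  # same detection rule applied to generator noise vs raw rnorm traces:
  # the two false-positive rates must agree within Monte-Carlo error
  n <- 800L
  ss <- gen_epsc_sweeps(quick_epsc_config(p_failure = 1, noise_sd_pA = 2,
                                          n_sweeps = n, seed = 3))
  fp_impl <- mean(detect_events(ss, k_sd = 3, floor_pA = 0)$is_success)
  t <- ss$time_ms
  # oracle applies the same rule (0.5 ms boxcar, max |deviation| in the
  # window vs 3 x baseline SD) to raw Gaussian traces, smoothing by cumsum
  kw <- round(0.5 / ss$dt_ms)
  set.seed(4)
  fp_oracle <- mean(vapply(seq_len(n), function(i) {
    y <- rnorm(length(t), sd = 2)
    cs <- cumsum(c(0, y))
    ys <- (cs[(kw + 1):length(cs)] - cs[1:(length(cs) - kw)]) / kw
    tm <- t[seq_along(ys) + floor(kw / 2)]
    b <- ys[tm < 0]
    win <- ys[tm >= 1 & tm <= 15]
    max(abs(win - mean(b))) > 3 * sd(b)
  }, logical(1)))
  se <- sqrt(fp_oracle * (1 - fp_oracle) / n + 1e-6)
  expect_lt(abs(fp_impl - fp_oracle), 4 * se + 0.02)
})

test_that("series-resistance QC applies the 20% whole-experiment rule", {
  expect_true(all(qc_series_resistance(rep(15, 10))))
  expect_false(any(qc_series_resistance(c(15, 16, 18.5))))  # +23%
  expect_true(all(qc_series_resistance(c(15, 16, 17.9))))   # +19.3%
  expect_error(qc_series_resistance(c(15, -2)),
               class = "barreldev_data_error")
  expect_error(qc_series_resistance(numeric(0)),
               class = "barreldev_data_error")
})

test_that("mean_epsc averages successes only and is failure-invariant", {
  ss <- gen_epsc_sweeps(quick_epsc_config(noise_sd_pA = 0, p_failure = 0,
                                          amp_cv = 0, ampa_amp_pA = 40,
                                          nmda_amp_pA = 0, n_sweeps = 4,
                                          seed = 5))
  avg <- mean_epsc(ss)
  # identical success sweeps: average equals any single sweep
  expect_equal(avg$mean_current_pA, ss$currents[1, ])
  expect_equal(avg$mean_amp_pA, -40, tolerance = 0.01)

  # appending failure (noise-only) trials must not change the average
  ss_aug <- ss
  ss_aug$currents <- rbind(ss$currents, matrix(0, 3, ncol(ss$currents)))
  ss_aug$sweep_id <- seq_len(nrow(ss_aug$currents))
  calls <- detect_events(ss_aug)
  expect_identical(sum(calls$is_success), 4L)
  avg2 <- mean_epsc(ss_aug, calls)
  expect_equal(avg2$mean_current_pA, avg$mean_current_pA)
  expect_equal(avg2$n_fail, 3L)

  # arithmetic of the mean success peak
  peaks <- c(-30, -40, -50)
  fake_calls <- data.frame(is_success = c(TRUE, TRUE, TRUE, FALSE),
                           peak_amp_pA = c(peaks, 0))
  ss3 <- ss
  ss3$currents <- ss$currents[c(1, 2, 3, 4), ]
  expect_equal(mean_epsc(ss3, fake_calls)$mean_amp_pA, -40)

  # all failures -> insufficient data
  none <- data.frame(is_success = rep(FALSE, 4), peak_amp_pA = rep(0, 4))
  expect_error(mean_epsc(ss, none),
               class = "barreldev_insufficient_data_error")

  # generator-truth recovery of the mean success amplitude
  ssn <- gen_epsc_sweeps(quick_epsc_config(noise_sd_pA = 0, p_failure = 0,
                                           amp_cv = 0.2, ampa_amp_pA = 40,
                                           nmda_amp_pA = 0, n_sweeps = 100,
                                           seed = 6))
  avg_n <- mean_epsc(ssn)
  se <- 40 * 0.2 / sqrt(100)
  expect_lt(abs(abs(avg_n$mean_amp_pA) - 40), 2 * se)
})

test_that("fit_decay recovers exact exponentials and flags degenerate input", {
  t <- seq(-10, 300, by = 0.1)
  y <- ifelse(t >= 0, 60 * exp(-t / 50), 0)
  fit <- fit_decay(t, y, fit_start_ms = 0, fit_end_ms = 300)
  expect_true(fit$converged)
  expect_equal(fit$tau_ms, 50, tolerance = 0.01 * 50)

  flat <- fit_decay(t, rep(0, length(t)), fit_start_ms = 0, fit_end_ms = 300)
  expect_false(flat$converged)
})

test_that("fit_decay is scale- and shift-equivariant", {
  t <- seq(-10, 300, by = 0.1)
  set.seed(7)
  y <- ifelse(t >= 0, -45 * exp(-t / 60), 0) + rnorm(length(t), sd = 1)
  f0 <- fit_decay(t, y, fit_start_ms = 0)
  f_scaled <- fit_decay(t, 3 * y, fit_start_ms = 0)
  f_shifted <- fit_decay(t, y + 25, fit_start_ms = 0)
  expect_true(f0$converged && f_scaled$converged && f_shifted$converged)
  expect_equal(f_scaled$tau_ms, f0$tau_ms, tolerance = 1e-6)
  expect_equal(f_scaled$amp_pA, 3 * f0$amp_pA, tolerance = 1e-6)
  expect_equal(f_shifted$tau_ms, f0$tau_ms, tolerance = 1e-6)
  expect_equal(f_shifted$offset_pA, f0$offset_pA + 25, tolerance = 1e-6)
})

test_that("decay tau is recovered across the physiological range", {
  # median recovered tau from replicate synthetic experiments within 10%
  taus <- c(30, 43, 51, 71)
  for (tau in taus) {
    rec <- vapply(1:20, function(r) {
      ss <- gen_epsc_sweeps(epsc_gen_config(
        holding_mV = 40, ampa_amp_pA = 0, nmda_amp_pA = 34,
        nmda_decay_ms = tau, p_failure = 0.3, n_sweeps = 25,
        noise_sd_pA = 2, seed = 1000 * tau + r))
      avg <- mean_epsc(ss)
      fit_decay(avg$time_ms, avg$mean_current_pA, fit_end_ms = 300)$tau_ms
    }, numeric(1))
    expect_lt(abs(stats::median(rec) - tau) / tau, 0.10)
  }
})

test_that("NMDA:AMPA ratio and ifenprodil inhibition arithmetic", {
  expect_identical(nmda_ampa_ratio(0, 40), 0)
  expect_identical(nmda_ampa_ratio(40, 40), 1)
  expect_error(nmda_ampa_ratio(10, 0), class = "barreldev_data_error")

  expect_identical(ifenprodil_inhibition(100, 100), 0)
  expect_identical(ifenprodil_inhibition(100, 0), 100)
  expect_equal(ifenprodil_inhibition(100, 34), 66)
  expect_warning(out <- ifenprodil_inhibition(50, 60), "clipped")
  expect_identical(out, 0)
  expect_error(ifenprodil_inhibition(0, 10), class = "barreldev_data_error")
})

test_that("a configured NMDA:AMPA generator ratio is recovered end to end", {
  # +40 mV mean peak configured at 0.84 x the -70 mV mean peak
  ss70 <- gen_epsc_sweeps(epsc_gen_config(
    holding_mV = -70, ampa_amp_pA = 40, nmda_amp_pA = 0,
    p_failure = 0.3, n_sweeps = 60, noise_sd_pA = 1, seed = 21))
  ss40 <- gen_epsc_sweeps(epsc_gen_config(
    holding_mV = 40, ampa_amp_pA = 0, nmda_amp_pA = 0.84 * 40,
    p_failure = 0.3, n_sweeps = 60, noise_sd_pA = 1, seed = 22))
  row <- analyze_experiment(ss70, ss40)
  expect_equal(row$nmda_ampa_ratio, 0.84, tolerance = 0.08)
})
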