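# EPSC sweep analysis ----------------------------------------------------------

#' Extract one sweep from a sweep set
#'
#' @param ss A `sweep_set`.
#' @param i Sweep index.
#' @return A list with `time_ms`, `current_pA`, `holding_mV`, `dt_ms` and
#'   identifiers.
#' @export
get_sweep <- function(ss, i) {
  stopifnot(inherits(ss, "sweep_set"))
  if (i < 1 || i > nrow(ss$currents)) abort_bounds("sweep index out of range")
  list(time_ms = ss$time_ms, current_pA = ss$currents[i, ],
       holding_mV = ss$holding_mV, dt_ms = ss$dt_ms,
       experiment_id = ss$experiment_id, sweep_id = ss$sweep_id[i])
}

#' Classify one sweep as success or failure and measure its peak
#'
#' The baseline mean and SD are estimated from the pre-stimulus window
#' (t < 0). The sweep is a success iff the magnitude of the
#' baseline-subtracted extremum inside `response_window_ms` exceeds
#' `max(k_sd * baseline_sd, floor_pA)`. The sign convention is physiological:
#' inward currents are negative.
#'
#' The success criterion is a conventional minimal-stimulation rule; both the
#' SD multiplier and the absolute floor are exposed so the operating point
#' can be audited.
#'
#' Before measurement the trace is smoothed with a short boxcar
#' (`smooth_ms`, default 0.5 ms), mirroring the low-pass filtering of the
#' recording chain; this suppresses single-sample noise excursions that
#' would otherwise dominate an extremum search at 10 kHz while attenuating
#' the EPSC peak by well under 1%.
#'
#' @param sweep A sweep (list with `time_ms` and `current_pA`), e.g. from
#'   [get_sweep()].
#' @param response_window_ms Length-2 numeric, post-stimulus search window
#'   (ms); default 1-15 ms.
#' @param k_sd Baseline-SD multiplier of the detection threshold.
#' @param floor_pA Absolute detection floor (pA).
#' @param smooth_ms Boxcar smoothing width (ms); 0 disables smoothing.
#' @return An `event_call`: list with `is_success`, `peak_amp_pA` (signed,
#'   baseline-subtracted), `peak_time_ms`, `baseline_mean_pA`,
#'   `baseline_sd_pA`, `threshold_pA`.
#' @export
detect_event <- function(sweep, response_window_ms = c(1, 15), k_sd = 3,
                         floor_pA = 5, smooth_ms = 0.5) {
  t <- sweep$time_ms; y <- sweep$current_pA
  dt <- stats::median(diff(t))
  kw <- max(1L, round(smooth_ms / dt))
  if (kw > 1L) {
    y <- as.numeric(stats::filter(y, rep(1 / kw, kw), sides = 2))
    ok <- is.finite(y)
    t <- t[ok]; y <- y[ok]
  }
  if (length(response_window_ms) != 2L ||
      response_window_ms[1] >= response_window_ms[2])
    abort_config("response_window_ms", "must be an increasing length-2 window")
  if (response_window_ms[2] > max(t) || response_window_ms[1] < min(t))
    abort_bounds("response window lies outside the recorded trace")
  base_idx <- which(t < 0)
  if (length(base_idx) < 10L)
    abort_data("baseline window has fewer than 10 samples")
  bmean <- mean(y[base_idx])
  bsd <- stats::sd(y[base_idx])
  win <- which(t >= response_window_ms[1] & t <= response_window_ms[2])
  d <- y[win] - bmean
  i_ext <- which.max(abs(d))
  peak <- d[i_ext]
  thr <- max(k_sd * bsd, floor_pA)
  structure(list(
    is_success = abs(peak) > thr,
    peak_amp_pA = peak,
    peak_time_ms = t[win][i_ext],
    baseline_mean_pA = bmean,
    baseline_sd_pA = bsd,
    threshold_pA = thr
  ), class = "event_call")
}

#' Classify every sweep in a set
#'
#' @inheritParams detect_event
#' @param ss A `sweep_set`.
#' @return A data frame with one row per sweep: `sweep_id`, `is_success`,
#'   `peak_amp_pA`, `peak_time_ms`, `baseline_mean_pA`, `baseline_sd_pA`.
#' @export
detect_events <- function(ss, response_window_ms = c(1, 15), k_sd = 3,
                          floor_pA = 5, smooth_ms = 0.5) {
  stopifnot(inherits(ss, "sweep_set"))
  calls <- lapply(seq_len(nrow(ss$currents)), function(i)
    detect_event(get_sweep(ss, i), response_window_ms, k_sd, floor_pA,
                 smooth_ms))
  data.frame(
    sweep_id = ss$sweep_id,
    is_success = vapply(calls, `[[`, logical(1), "is_success"),
    peak_amp_pA = vapply(calls, `[[`, numeric(1), "peak_amp_pA"),
    peak_time_ms = vapply(calls, `[[`, numeric(1), "peak_time_ms"),
    baseline_mean_pA = vapply(calls, `[[`, numeric(1), "baseline_mean_pA"),
    baseline_sd_pA = vapply(calls, `[[`, numeric(1), "baseline_sd_pA")
  )
}

#' Series-resistance quality control
#'
#' Whole-experiment rejection rule: if the series resistance deviates from
#' its initial value by more than `max_change` (default 20%) at any point
#' during data collection the experiment is rejected and every sweep is
#' masked out; otherwise all sweeps are kept.
#'
#' @param values_MOhm Per-sweep series resistance values (MOhm).
#' @param max_change Maximum tolerated fractional change from the first value.
#' @return Logical keep-mask of the same length (all `TRUE` or all `FALSE`).
#' @export
qc_series_resistance <- function(values_MOhm, max_change = 0.2) {
  if (length(values_MOhm) < 1L) abort_data("need at least one series-resistance value")
  if (any(!is.finite(values_MOhm)) || any(values_MOhm <= 0))
    abort_data("series resistance values must be positive and finite")
  dev <- abs(values_MOhm - values_MOhm[1]) / values_MOhm[1]
  rep(max(dev) <= max_change, length(values_MOhm))
}

#' Failure-excluded average EPSC
#'
#' Pointwise mean of success sweeps only, as shown in the example traces:
#' failures are excluded before averaging so the mean amplitude estimates the
#' potency (success amplitude), not the efficacy.
#'
#' @param ss A `sweep_set`.
#' @param calls Data frame from [detect_events()] (recomputed if `NULL`).
#' @return List with `time_ms`, `mean_current_pA`, `mean_amp_pA` (mean of
#'   success peak amplitudes, signed), `n_success`, `n_fail`.
#' @export
mean_epsc <- function(ss, calls = NULL) {
  stopifnot(inherits(ss, "sweep_set"))
  if (is.null(calls)) calls <- detect_events(ss)
  ok <- calls$is_success
  if (!any(ok))
    abort_insufficient("no success sweeps: cannot form a failure-excluded average")
  avg <- colMeans(ss$currents[ok, , drop = FALSE])
  list(time_ms = ss$time_ms, mean_current_pA = avg,
       mean_amp_pA = mean(calls$peak_amp_pA[ok]),
       n_success = sum(ok), n_fail = sum(!ok))
}

#' Fit a single exponential to an EPSC decay
#'
#' Fits `A * exp(-(t - t_start)/tau) + C` by Levenberg-Marquardt least
#' squares over `[fit_start_ms, fit_end_ms]`. By default the window starts at
#' twice the post-stimulus peak latency: at the extremum itself the rising
#' phase of a difference-of-exponentials EPSC has not fully decayed and
#' contaminates a single-exponential fit by several percent, whereas one
#' additional peak-latency later the residual rise component is negligible.
#' The initial tau is taken from the time at which the offset-corrected
#' trace first falls to 1/e of its starting value; A and C start at the
#' start-minus-tail and tail values. A fit is reported unconverged if the
#' optimiser fails or the fitted tau leaves (0.1, 1e4) ms.
#'
#' @param time_ms,current_pA Trace samples; stimulus at t = 0.
#' @param fit_start_ms Start of the fit window; default `NULL` places it at
#'   twice the latency of the post-stimulus extremum.
#' @param fit_end_ms End of the fit window (ms).
#' @return A `decay_fit`: list with `tau_ms`, `amp_pA`, `offset_pA`,
#'   `window`, `residual_norm`, `converged` and (when unconverged) a
#'   `diagnostic` message.
#' @export
fit_decay <- function(time_ms, current_pA, fit_start_ms = NULL,
                      fit_end_ms = 300) {
  t <- time_ms; y <- current_pA
  post <- which(t >= 0)
  auto_start <- is.null(fit_start_ms)
  if (auto_start) {
    i_pk <- post[which.max(abs(y[post] - stats::median(y[t < 0])))]
    fit_start_ms <- 2 * t[i_pk]
  }
  if (fit_end_ms > max(t)) fit_end_ms <- max(t)
  win <- which(t >= fit_start_ms & t <= fit_end_ms)
  fail <- function(msg) structure(list(
    tau_ms = NA_real_, amp_pA = NA_real_, offset_pA = NA_real_,
    window = c(fit_start_ms, fit_end_ms), residual_norm = NA_real_,
    converged = FALSE, diagnostic = msg), class = "decay_fit")
  if (length(win) < 20L) {
    if (auto_start) return(fail("automatic fit window has fewer than 20 samples"))
    abort_data("decay fit window has fewer than 20 samples")
  }
  ts <- t[win] - fit_start_ms
  ys <- y[win]
  c0 <- mean(ys[ts >= 0.9 * max(ts)])
  a0 <- ys[1] - c0
  if (!is.finite(a0) || abs(a0) < .Machine$double.eps^0.5)
    return(fail("no decaying transient in the fit window"))
  # initial tau from the 1/e crossing of the offset-corrected trace
  rel <- (ys - c0) / a0
  cross <- which(rel <= exp(-1))
  tau0 <- if (length(cross)) max(ts[cross[1]], 2 * (ts[2] - ts[1]))
          else max(ts) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ A * exp(-ts / tau) + C,
      start = list(A = a0, tau = tau0, C = c0),
      lower = c(A = -Inf, tau = 0.1, C = -Inf),
      upper = c(A = Inf, tau = 1e4, C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  if (!is.finite(tau) || tau <= 0.1 + 1e-9 || tau >= 1e4 - 1e-6)
    return(fail(sprintf("fitted tau = %.3g ms outside (0.1, 1e4)", tau)))
  structure(list(
    tau_ms = tau, amp_pA = unname(cf["A"]), offset_pA = unname(cf["C"]),
    window = c(fit_start_ms, fit_end_ms),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    converged = TRUE, diagnostic = NULL
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<decay_fit> tau = %.3g ms, A = %.3g pA, offset = %.3g pA (window %g-%g ms)\n",
                x$tau_ms, x$amp_pA, x$offset_pA, x$window[1], x$window[2]))
  else
    cat(sprintf("<decay_fit> NOT converged: %s\n", x$diagnostic))
  invisible(x)
}

#' NMDA:AMPA amplitude ratio
#'
#' @param amp_plus40 NMDA-mediated EPSC amplitude at +40 mV (pA, magnitude).
#' @param amp_minus70 AMPA-mediated EPSC amplitude at -70 mV (pA, magnitude).
#' @return `amp_plus40 / amp_minus70`.
#' @export
nmda_ampa_ratio <- function(amp_plus40, amp_minus70) {
  if (!is.finite(amp_minus70) || amp_minus70 <= 0)
    abort_data("AMPA amplitude at -70 mV must be positive; pass the failure-excluded mean peak magnitude")
  if (!is.finite(amp_plus40) || amp_plus40 < 0)
    abort_data("NMDA amplitude must be a non-negative magnitude")
  amp_plus40 / amp_minus70
}

#' NMDA amplitude of an averaged +40 mV trace
#'
#' Two conventions: the peak of the failure-excluded average (default) or the
#' mean current over a fixed late window (default 40-60 ms post-stimulus),
#' where the AMPA component has fully decayed.
#'
#' @param time_ms,mean_current_pA Averaged trace.
#' @param method `"peak"` or `"late_window"`.
#' @param window_ms Late window (ms), used when `method = "late_window"`.
#' @return Amplitude magnitude (pA) relative to the pre-stimulus baseline.
#' @export
nmda_amplitude <- function(time_ms, mean_current_pA,
                           method = c("peak", "late_window"),
                           window_ms = c(40, 60)) {
  method <- match.arg(method)
  base <- mean(mean_current_pA[time_ms < 0])
  if (method == "peak") {
    post <- time_ms >= 0
    max(abs(mean_current_pA[post] - base))
  } else {
    win <- time_ms >= window_ms[1] & time_ms <= window_ms[2]
    if (!any(win)) abort_bounds("late window lies outside the trace")
    abs(mean(mean_current_pA[win]) - base)
  }
}

#' Percent inhibition by ifenprodil
#'
#' @param amp_control,amp_drug NMDA EPSC amplitudes (pA, magnitudes) before
#'   and during drug application.
#' @return Percent inhibition `100 * (1 - amp_drug/amp_control)`, clipped to
#'   `[0, 100]` with a warning if the drug amplitude exceeds control.
#' @export
ifenprodil_inhibition <- function(amp_control, amp_drug) {
  if (!is.finite(amp_control) || amp_control <= 0)
    abort_data("control amplitude must be a positive magnitude")
  if (!is.finite(amp_drug) || amp_drug < 0)
    abort_data("drug amplitude must be a non-negative magnitude")
  pct <- 100 * (1 - amp_drug / amp_control)
  if (pct < 0) {
    warning("drug amplitude exceeds control; inhibition clipped to 0%")
    pct <- 0
  }
  min(pct, 100)
}

#' Analyse one minimal-stimulation experiment end to end
#'
#' Convenience wrapper: event detection, failure-excluded averaging, decay
#' fit on the average, and (when both holding potentials are supplied) the
#' NMDA:AMPA ratio.
#'
#' @param ss_minus70 `sweep_set` recorded at -70 mV.
#' @param ss_plus40 Optional `sweep_set` recorded at +40 mV.
#' @param response_window_ms,k_sd,floor_pA Detection parameters, see
#'   [detect_event()].
#' @param fit_end_ms Decay-fit window ends per holding potential: named
#'   vector `c(minus70 = 50, plus40 = 300)`.
#' @param nmda_method Amplitude convention at +40 mV, see [nmda_amplitude()].
#' @return One-row data frame: `experiment_id`, `animal_id`, `n_success`,
#'   `n_fail`, `failure_rate`, `mean_amp_pA`, `tau_ms` (AMPA, -70 mV),
#'   `nmda_amp_pA`, `nmda_tau_ms`, `nmda_ampa_ratio`.
#' @export
analyze_experiment <- function(ss_minus70, ss_plus40 = NULL,
                               response_window_ms = c(1, 15), k_sd = 3,
                               floor_pA = 5,
                               fit_end_ms = c(minus70 = 50, plus40 = 300),
                               nmda_method = "peak") {
  calls <- detect_events(ss_minus70, response_window_ms, k_sd, floor_pA)
  avg <- mean_epsc(ss_minus70, calls)
  fit <- fit_decay(avg$time_ms, avg$mean_current_pA,
                   fit_end_ms = fit_end_ms[["minus70"]])
  nmda_amp <- nmda_tau <- ratio <- NA_real_
  if (!is.null(ss_plus40)) {
    calls40 <- detect_events(ss_plus40, response_window_ms, k_sd, floor_pA)
    avg40 <- mean_epsc(ss_plus40, calls40)
    nmda_amp <- nmda_amplitude(avg40$time_ms, avg40$mean_current_pA,
                               method = nmda_method)
    fit40 <- fit_decay(avg40$time_ms, avg40$mean_current_pA,
                       fit_end_ms = fit_end_ms[["plus40"]])
    nmda_tau <- if (fit40$converged) fit40$tau_ms else NA_real_
    ratio <- nmda_ampa_ratio(nmda_amp, abs(avg$mean_amp_pA))
  }
  data.frame(
    experiment_id = ss_minus70$experiment_id,
    animal_id = ss_minus70$animal_id,
    n_success = avg$n_success, n_fail = avg$n_fail,
    failure_rate = avg$n_fail / (avg$n_success + avg$n_fail),
    mean_amp_pA = avg$mean_amp_pA,
    tau_ms = if (fit$converged) fit$tau_ms else NA_real_,
    nmda_amp_pA = nmda_amp, nmda_tau_ms = nmda_tau,
    nmda_ampa_ratio = ratio
  )
}

#' Within-animal averaging of per-experiment values
#'
#' Statistics are computed on animals, not cells: per-experiment values are
#' first averaged within each animal and all group tests operate on the
#' resulting one-value-per-animal table.
#'
#' @param df Data frame with an `animal_id` column.
#' @param value_cols Columns to average (default: all numeric columns).
#' @return Data frame with one row per animal.
#' @export
within_animal_means <- function(df, value_cols = NULL) {
  if (!"animal_id" %in% names(df)) abort_schema("missing column animal_id")
  if (is.null(value_cols))
    value_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  out <- stats::aggregate(df[value_cols], by = list(animal_id = df$animal_id),
                          FUN = function(v) mean(v, na.rm = TRUE))
  out[order(out$animal_id), , drop = FALSE]
}
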