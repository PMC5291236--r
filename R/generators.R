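# Synthetic-data generators ---------------------------------------------------
#
# These generators emulate the statistical structure of minimal-stimulation
# thalamocortical recordings and barrel-cortex histology so every analysis
# stage can be exercised and validated without external data. Defaults are the
# published calibration points for wild-type recordings at the start of the
# critical period: failure rate 0.48 over ~28 trials per experiment, shared-
# axon coincident-success proportion 0.92, AMPA decay tau 3.3 ms, NMDA decay
# tau 71 ms, minimal-stimulation EPSC amplitude ~40 pA, and a barrel
# wall:hollow cell-density ratio of 1.6.

#' Configuration for synthetic EPSC sweep generation
#'
#' Builds and validates the parameter set for [gen_epsc_sweeps()]. Each sweep
#' covers `[-pre_ms, post_ms]` around the stimulus at t = 0, sampled every
#' `dt_ms` (default 0.1 ms, i.e. 10 kHz digitization). A trial is a failure
#' (noise only) with probability `p_failure`; successes contain a
#' difference-of-exponentials EPSC whose peak magnitude is set by
#' `ampa_amp_pA` / `nmda_amp_pA` and scaled per trial by a lognormal factor
#' with unit mean and coefficient of variation `amp_cv`.
#'
#' At a holding potential of -70 mV the EPSC is inward (negative) and the
#' NMDA component is suppressed to `nmda_residual_minus70` (default 0, the
#' full-Mg-block approximation); at +40 mV the EPSC is outward (positive) and
#' both components contribute.
#'
#' @param dt_ms Sample interval (ms).
#' @param pre_ms,post_ms Baseline and response window durations (ms).
#' @param ampa_amp_pA,nmda_amp_pA Component peak amplitudes (pA, magnitudes).
#' @param ampa_rise_ms,ampa_decay_ms,nmda_rise_ms,nmda_decay_ms Kinetic time
#'   constants (ms); each decay constant must exceed its rise constant.
#' @param holding_mV Holding potential, -70 or +40.
#' @param p_failure Bernoulli failure probability per trial.
#' @param amp_cv Trial-to-trial coefficient of variation of the amplitude
#'   scale factor.
#' @param noise_sd_pA Gaussian recording-noise SD (pA).
#' @param nmda_residual_minus70 Fraction of the NMDA component present at
#'   -70 mV.
#' @param n_sweeps Number of trials.
#' @param seed RNG seed (integer) or `NULL` to use the current stream.
#' @param experiment_id,animal_id Identifiers carried into outputs.
#' @return A validated list of class `"epsc_gen_config"`.
#' @export
epsc_gen_config <- function(dt_ms = 0.1, pre_ms = 20, post_ms = 300,
                            ampa_amp_pA = 40, nmda_amp_pA = 34,
                            ampa_rise_ms = 0.5, ampa_decay_ms = 3.3,
                            nmda_rise_ms = 5, nmda_decay_ms = 71,
                            holding_mV = -70, p_failure = 0.48,
                            amp_cv = 0.2, noise_sd_pA = 2,
                            nmda_residual_minus70 = 0,
                            n_sweeps = 28, seed = NULL,
                            experiment_id = "exp1", animal_id = "animal1") {
  check_pos(dt_ms, "dt_ms")
  check_pos(pre_ms, "pre_ms")
  check_pos(post_ms, "post_ms")
  check_nonneg(ampa_amp_pA, "ampa_amp_pA")
  check_nonneg(nmda_amp_pA, "nmda_amp_pA")
  check_pos(ampa_rise_ms, "ampa_rise_ms")
  check_pos(nmda_rise_ms, "nmda_rise_ms")
  if (ampa_decay_ms <= ampa_rise_ms)
    abort_config("ampa_decay_ms", "must exceed ampa_rise_ms")
  if (nmda_decay_ms <= nmda_rise_ms)
    abort_config("nmda_decay_ms", "must exceed nmda_rise_ms")
  if (!holding_mV %in% c(-70, 40))
    abort_config("holding_mV", "must be -70 or 40")
  check_prob(p_failure, "p_failure")
  check_nonneg(amp_cv, "amp_cv")
  check_nonneg(noise_sd_pA, "noise_sd_pA")
  check_prob(nmda_residual_minus70, "nmda_residual_minus70")
  n_sweeps <- check_count(n_sweeps, "n_sweeps")
  structure(list(
    dt_ms = dt_ms, pre_ms = pre_ms, post_ms = post_ms,
    ampa_amp_pA = ampa_amp_pA, nmda_amp_pA = nmda_amp_pA,
    ampa_rise_ms = ampa_rise_ms, ampa_decay_ms = ampa_decay_ms,
    nmda_rise_ms = nmda_rise_ms, nmda_decay_ms = nmda_decay_ms,
    holding_mV = holding_mV, p_failure = p_failure, amp_cv = amp_cv,
    noise_sd_pA = noise_sd_pA,
    nmda_residual_minus70 = nmda_residual_minus70,
    n_sweeps = n_sweeps, seed = seed,
    experiment_id = experiment_id, animal_id = animal_id
  ), class = "epsc_gen_config")
}

# Unit-peak difference-of-exponentials waveform on t >= 0 (t in ms).
# w(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / w(t*), with the analytic peak at
# t* = tau_d*tau_r/(tau_d - tau_r) * log(tau_d/tau_r), so a configured
# amplitude is the exact extremum of the noiseless waveform.
epsc_kernel <- function(t, tau_rise, tau_decay) {
  stopifnot(tau_decay > tau_rise)
  t_peak <- tau_decay * tau_rise / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  w_peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  w <- numeric(length(t))
  pos <- t >= 0
  w[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / w_peak
  w
}

#' Generate a set of synthetic EPSC sweeps
#'
#' @param config An [epsc_gen_config()].
#' @return A `sweep_set`: list with `time_ms` (shared time base), `currents`
#'   (n_sweeps x n_samples matrix, pA), `holding_mV`, `dt_ms`, identifiers,
#'   optional `series_resistance_MOhm`, and a `truth` list recording which
#'   trials were generated as failures and their amplitude scale factors.
#' @export
gen_epsc_sweeps <- function(config) {
  if (!inherits(config, "epsc_gen_config"))
    config <- do.call(epsc_gen_config, as.list(config))
  with_seed(config$seed, {
    time_ms <- seq(-config$pre_ms, config$post_ms, by = config$dt_ms)
    n <- config$n_sweeps
    w_ampa <- epsc_kernel(time_ms, config$ampa_rise_ms, config$ampa_decay_ms)
    w_nmda <- epsc_kernel(time_ms, config$nmda_rise_ms, config$nmda_decay_ms)
    shape <- if (config$holding_mV == -70) {
      -(config$ampa_amp_pA * w_ampa +
          config$nmda_residual_minus70 * config$nmda_amp_pA * w_nmda)
    } else {
      config$ampa_amp_pA * w_ampa + config$nmda_amp_pA * w_nmda
    }
    is_failure <- stats::runif(n) < config$p_failure
    amp_scale <- if (config$amp_cv > 0) {
      sdlog <- sqrt(log1p(config$amp_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n)
    currents <- matrix(
      stats::rnorm(n * length(time_ms), sd = config$noise_sd_pA),
      nrow = n
    )
    for (i in which(!is_failure))
      currents[i, ] <- currents[i, ] + amp_scale[i] * shape
    structure(list(
      time_ms = time_ms,
      currents = currents,
      holding_mV = config$holding_mV,
      dt_ms = config$dt_ms,
      experiment_id = config$experiment_id,
      animal_id = config$animal_id,
      sweep_id = seq_len(n),
      series_resistance_MOhm = NULL,
      truth = list(is_failure = is_failure, amp_scale = amp_scale)
    ), class = "sweep_set")
  })
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %s (%s): %d sweeps x %d samples at %.3g kHz, holding %g mV\n",
    x$experiment_id, x$animal_id, nrow(x$currents), ncol(x$currents),
    1 / x$dt_ms, x$holding_mV))
  invisible(x)
}

#' Configuration for paired-cell trial outcome generation
#'
#' In shared mode a single presynaptic axon releases with probability
#' `p_release` per trial and each cell detects a release with probability
#' `detect_a` / `detect_b`, so coincident successes are common. In
#' independent mode the two cells succeed independently with probabilities
#' `p_a`, `p_b` and coincidences occur only at chance.
#'
#' @param n_trials Number of stimulation trials.
#' @param shared Logical: common-axon (TRUE) or independent-axon topology.
#' @param p_release Per-trial release probability (shared mode).
#' @param detect_a,detect_b Conditional success probabilities given release.
#' @param p_a,p_b Independent per-cell success probabilities.
#' @param seed RNG seed or `NULL`.
#' @param experiment_id,animal_id Identifiers.
#' @return A validated list of class `"dual_cell_gen_config"`.
#' @export
dual_cell_gen_config <- function(n_trials = 28, shared = TRUE,
                                 p_release = 0.52, detect_a = 1,
                                 detect_b = 0.92, p_a = 0.52, p_b = 0.52,
                                 seed = NULL, experiment_id = "pair1",
                                 animal_id = "animal1") {
  n_trials <- check_count(n_trials, "n_trials")
  if (!is.logical(shared) || length(shared) != 1L || is.na(shared))
    abort_config("shared", "must be TRUE or FALSE")
  check_prob(p_release, "p_release")
  check_prob(detect_a, "detect_a")
  check_prob(detect_b, "detect_b")
  check_prob(p_a, "p_a")
  check_prob(p_b, "p_b")
  structure(list(
    n_trials = n_trials, shared = shared, p_release = p_release,
    detect_a = detect_a, detect_b = detect_b, p_a = p_a, p_b = p_b,
    seed = seed, experiment_id = experiment_id, animal_id = animal_id
  ), class = "dual_cell_gen_config")
}

#' Generate success/failure outcomes for a simultaneously recorded cell pair
#'
#' @param config A [dual_cell_gen_config()].
#' @return A `trial_outcomes` object: logical vectors `success_a`,
#'   `success_b` plus identifiers and the generating topology.
#' @export
gen_dual_cell <- function(config) {
  if (!inherits(config, "dual_cell_gen_config"))
    config <- do.call(dual_cell_gen_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n_trials
    if (config$shared) {
      release <- stats::runif(n) < config$p_release
      a <- release & (stats::runif(n) < config$detect_a)
      b <- release & (stats::runif(n) < config$detect_b)
    } else {
      a <- stats::runif(n) < config$p_a
      b <- stats::runif(n) < config$p_b
    }
    trial_outcomes(a, b, experiment_id = config$experiment_id,
                   animal_id = config$animal_id)
  })
}

#' Construct a paired-trial outcome object
#'
#' @param success_a,success_b Equal-length logical vectors of per-trial
#'   success flags for the two cells.
#' @param experiment_id,animal_id Identifiers.
#' @return A `trial_outcomes` object.
#' @export
trial_outcomes <- function(success_a, success_b, experiment_id = "pair1",
                           animal_id = "animal1") {
  success_a <- as.logical(success_a)
  success_b <- as.logical(success_b)
  if (length(success_a) != length(success_b))
    abort_data(sprintf(
      "trial outcome vectors differ in length (%d vs %d)",
      length(success_a), length(success_b)))
  if (length(success_a) < 1L)
    abort_data("trial outcome vectors must have length >= 1")
  if (anyNA(success_a) || anyNA(success_b))
    abort_data("trial outcome vectors must not contain NA")
  structure(list(success_a = success_a, success_b = success_b,
                 experiment_id = experiment_id, animal_id = animal_id),
            class = "trial_outcomes")
}

#' Configuration for synthetic barrel nuclei point fields
#'
#' Emulates a stack of confocal optical sections through one barrel: nuclei
#' are placed by a homogeneous Poisson process with density `rho_hollow`
#' inside the cell-sparse hollow disc, `rho_wall` in the cell-dense wall
#' annulus, and `rho_outside` beyond the wall out to a square field of
#' half-width `field_half_um`.
#'
#' @param center_xy Barrel centre (um), length-2 numeric.
#' @param r_hollow,r_wall Hollow radius and wall outer radius (um);
#'   `0 < r_hollow < r_wall`.
#' @param rho_hollow,rho_wall,rho_outside Point densities (points/um^2).
#' @param n_sections Number of optical sections in the stack.
#' @param section_spacing_um Spacing between sections (um, default 3).
#' @param field_half_um Half-width of the square field containing the barrel.
#' @param seed RNG seed or `NULL`.
#' @return A validated list of class `"barrel_gen_config"`.
#' @export
barrel_gen_config <- function(center_xy = c(0, 0), r_hollow = 100,
                              r_wall = 150, rho_hollow = 0.02,
                              rho_wall = 0.032, rho_outside = 0.02,
                              n_sections = 5, section_spacing_um = 3,
                              field_half_um = NULL, seed = NULL) {
  if (!is.numeric(center_xy) || length(center_xy) != 2L || anyNA(center_xy))
    abort_config("center_xy", "must be a length-2 numeric")
  check_pos(r_hollow, "r_hollow")
  if (!is.numeric(r_wall) || length(r_wall) != 1L || r_wall <= r_hollow)
    abort_config("r_wall", "must exceed r_hollow")
  check_nonneg(rho_hollow, "rho_hollow")
  check_nonneg(rho_wall, "rho_wall")
  check_nonneg(rho_outside, "rho_outside")
  n_sections <- check_count(n_sections, "n_sections")
  check_pos(section_spacing_um, "section_spacing_um")
  if (is.null(field_half_um)) field_half_um <- 1.5 * r_wall
  if (field_half_um < r_wall)
    abort_config("field_half_um", "must be at least r_wall")
  structure(list(
    center_xy = center_xy, r_hollow = r_hollow, r_wall = r_wall,
    rho_hollow = rho_hollow, rho_wall = rho_wall,
    rho_outside = rho_outside, n_sections = n_sections,
    section_spacing_um = section_spacing_um,
    field_half_um = field_half_um, seed = seed
  ), class = "barrel_gen_config")
}

#' Generate a stack of synthetic nuclei point fields
#'
#' @param config A [barrel_gen_config()].
#' @return A `point_field`: list with `points` (data.frame `section`, `x_um`,
#'   `y_um`; sections indexed from 0) and `section_spacing_um`.
#' @export
gen_barrel_points <- function(config) {
  if (!inherits(config, "barrel_gen_config"))
    config <- do.call(barrel_gen_config, as.list(config))
  with_seed(config$seed, {
    cx <- config$center_xy[1]; cy <- config$center_xy[2]
    rh <- config$r_hollow; rw <- config$r_wall; hf <- config$field_half_um
    area_hollow <- pi * rh^2
    area_wall <- pi * (rw^2 - rh^2)
    area_outside <- (2 * hf)^2 - pi * rw^2
    secs <- vector("list", config$n_sections)
    for (s in seq_len(config$n_sections)) {
      # hollow: uniform in disc via sqrt radius trick
      nh <- stats::rpois(1, config$rho_hollow * area_hollow)
      r <- rh * sqrt(stats::runif(nh)); th <- stats::runif(nh, 0, 2 * pi)
      xh <- cx + r * cos(th); yh <- cy + r * sin(th)
      # wall annulus
      nw <- stats::rpois(1, config$rho_wall * area_wall)
      r <- sqrt(stats::runif(nw, rh^2, rw^2)); th <- stats::runif(nw, 0, 2 * pi)
      xw <- cx + r * cos(th); yw <- cy + r * sin(th)
      # outside: rejection from the square
      no <- stats::rpois(1, config$rho_outside * area_outside)
      xo <- yo <- numeric(0)
      while (length(xo) < no) {
        m <- max(16L, 2L * (no - length(xo)))
        x <- stats::runif(m, cx - hf, cx + hf)
        y <- stats::runif(m, cy - hf, cy + hf)
        keep <- (x - cx)^2 + (y - cy)^2 > rw^2
        xo <- c(xo, x[keep]); yo <- c(yo, y[keep])
      }
      xo <- xo[seq_len(no)]; yo <- yo[seq_len(no)]
      xs <- c(xh, xw, xo); ys <- c(yh, yw, yo)
      secs[[s]] <- data.frame(section = rep(s - 1L, length(xs)),
                              x_um = xs, y_um = ys)
    }
    point_field(do.call(rbind, secs),
                section_spacing_um = config$section_spacing_um)
  })
}

#' Construct a point field from a (section, x_um, y_um) table
#'
#' @param points Data frame with columns `section`, `x_um`, `y_um`.
#' @param section_spacing_um Optical section spacing (um).
#' @return A `point_field` object.
#' @export
point_field <- function(points, section_spacing_um = 3) {
  if (!all(c("section", "x_um", "y_um") %in% names(points)))
    abort_schema("point table must have columns section, x_um, y_um")
  if (nrow(points) > 0 && (!all(is.finite(points$x_um)) ||
                           !all(is.finite(points$y_um))))
    abort_data("point coordinates must be finite")
  structure(list(points = points, section_spacing_um = section_spacing_um),
            class = "point_field")
}

#' Configuration for synthetic traversing-axon segment fields
#'
#' Emulates labelled axons running radially across layer 4: the number of
#' axons traversing a region of interest is Poisson with mean `lambda`
#' (`lambda_centre` for barrel-centre ROIs, `lambda_septa` for septal ROIs).
#' Traversing segments cross both long edges of the ROI; `n_distractors`
#' short fragments fully interior to the ROI can be added to exercise the
#' traversal counting rule.
#'
#' @param lambda_centre,lambda_septa Expected traversing-axon counts per ROI.
#' @param segment_length_um Generated segment length (um); must exceed the
#'   ROI width for a traversal to be possible.
#' @param jitter_deg Maximum deviation (degrees) of a segment from the
#'   perpendicular to the ROI's long axis.
#' @param n_distractors Deterministic count of non-traversing interior
#'   fragments per ROI.
#' @param seed RNG seed or `NULL`.
#' @return A validated list of class `"axon_field_config"`.
#' @export
axon_field_config <- function(lambda_centre = 12.4, lambda_septa = 9.8,
                              segment_length_um = 60, jitter_deg = 10,
                              n_distractors = 0, seed = NULL) {
  check_nonneg(lambda_centre, "lambda_centre")
  check_nonneg(lambda_septa, "lambda_septa")
  check_pos(segment_length_um, "segment_length_um")
  check_nonneg(jitter_deg, "jitter_deg")
  n_distractors <- check_count(n_distractors, "n_distractors", min = 0L)
  if (jitter_deg >= 60)
    abort_config("jitter_deg", "must be below 60 degrees")
  structure(list(
    lambda_centre = lambda_centre, lambda_septa = lambda_septa,
    segment_length_um = segment_length_um, jitter_deg = jitter_deg,
    n_distractors = n_distractors, seed = seed
  ), class = "axon_field_config")
}

#' Generate axon segments traversing a region of interest
#'
#' @param config An [axon_field_config()].
#' @param roi An [roi_rect()].
#' @param compartment `"centre"` or `"septa"`; selects the Poisson mean.
#' @return Data frame of segments (`x1_um`, `y1_um`, `x2_um`, `y2_um`,
#'   `compartment`, `traversing`).
#' @export
gen_axon_segments <- function(config, roi,
                              compartment = c("centre", "septa")) {
  if (!inherits(config, "axon_field_config"))
    config <- do.call(axon_field_config, as.list(config))
  compartment <- match.arg(compartment)
  stopifnot(inherits(roi, "roi_rect"))
  lambda <- if (compartment == "centre") config$lambda_centre
            else config$lambda_septa
  with_seed(config$seed, {
    half_len <- config$segment_length_um / 2
    w2 <- roi$width_um / 2
    l2 <- roi$length_um / 2
    n_trav <- stats::rpois(1, lambda)
    segs <- matrix(numeric(0), ncol = 4)
    if (n_trav > 0) {
      got <- 0L
      rows <- matrix(NA_real_, n_trav, 4)
      while (got < n_trav) {
        th <- stats::runif(1, -config$jitter_deg, config$jitter_deg) * pi / 180
        dx <- sin(th) * half_len; dy <- cos(th) * half_len
        # keep both long-edge crossings inside the edge extent
        x_margin <- abs(tan(th)) * w2
        if (dy <= w2 || x_margin >= l2) next
        x0 <- stats::runif(1, -l2 + x_margin, l2 - x_margin)
        y0 <- stats::runif(1, -(dy - w2), dy - w2)
        got <- got + 1L
        rows[got, ] <- c(x0 - dx, y0 - dy, x0 + dx, y0 + dy)
      }
      segs <- rows
    }
    trav_flag <- rep(TRUE, nrow(segs))
    if (config$n_distractors > 0) {
      # short fragments strictly inside the ROI, never touching a long edge
      frag_half <- min(w2 * 0.4, half_len / 4)
      dd <- t(vapply(seq_len(config$n_distractors), function(i) {
        th <- stats::runif(1, 0, 2 * pi)
        x0 <- stats::runif(1, -l2 + frag_half, l2 - frag_half)
        y0 <- stats::runif(1, -(w2 - frag_half), w2 - frag_half)
        c(x0 - frag_half * cos(th), y0 - frag_half * sin(th),
          x0 + frag_half * cos(th), y0 + frag_half * sin(th))
      }, numeric(4)))
      segs <- rbind(segs, dd)
      trav_flag <- c(trav_flag, rep(FALSE, config$n_distractors))
    }
    if (nrow(segs) == 0L)
      return(data.frame(x1_um = numeric(0), y1_um = numeric(0),
                        x2_um = numeric(0), y2_um = numeric(0),
                        compartment = character(0), traversing = logical(0)))
    # rotate/translate from ROI frame into field coordinates
    a <- roi$angle_deg * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    p1 <- t(R %*% rbind(segs[, 1], segs[, 2])) +
      matrix(roi$center_xy, nrow(segs), 2, byrow = TRUE)
    p2 <- t(R %*% rbind(segs[, 3], segs[, 4])) +
      matrix(roi$center_xy, nrow(segs), 2, byrow = TRUE)
    data.frame(x1_um = p1[, 1], y1_um = p1[, 2],
               x2_um = p2[, 1], y2_um = p2[, 2],
               compartment = rep(compartment, nrow(segs)),
               traversing = trav_flag)
  })
}
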