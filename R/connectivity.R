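# Shared-axon inference from paired recordings ---------------------------------

#' Binomial coincidence test for shared presynaptic input
#'
#' Given per-trial success flags for two simultaneously recorded cells under
#' minimal stimulation, tests whether the number of trials in which both
#' cells responded exceeds the chance level implied by each cell's own
#' success rate. A stimulated axon is deemed to contact both cells when the
#' upper-tail binomial probability of the observed (or greater) coincidence
#' count falls below `alpha`.
#'
#' Two null formulations are provided. In `"joint"` mode (default) the
#' coincidence count over all `n` trials is referred to
#' Binomial(n, p_a_hat * p_b_hat). In `"conditional"` mode the count is
#' referred to Binomial(number of A-successes, p_b_hat), i.e. conditioning on
#' the trials in which cell A responded.
#'
#' @param outcomes A [trial_outcomes()] object.
#' @param alpha Classification level (default 0.05).
#' @param mode `"joint"` or `"conditional"`.
#' @return A `coincidence_result`: list with `n_trials`, `k_coincident`,
#'   `p_a_hat`, `p_b_hat`, `p_null`, `p_value`, `shared`, `alpha`, `mode`
#'   and identifiers.
#' @export
coincidence_test <- function(outcomes, alpha = 0.05,
                             mode = c("joint", "conditional")) {
  stopifnot(inherits(outcomes, "trial_outcomes"))
  mode <- match.arg(mode)
  check_prob(alpha, "alpha")
  a <- outcomes$success_a; b <- outcomes$success_b
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  k <- sum(a & b)
  p_a <- sa / n; p_b <- sb / n
  if (sa == 0L || sb == 0L) {
    # no successes in one cell: coincidence is impossible, trivially not shared
    p_null <- if (mode == "joint") p_a * p_b else p_b
    res <- list(p_value = 1, p_null = p_null)
  } else if (mode == "joint") {
    p_null <- p_a * p_b
    res <- list(p_value = stats::pbinom(k - 1, n, p_null, lower.tail = FALSE),
                p_null = p_null)
  } else {
    res <- list(p_value = stats::pbinom(k - 1, sa, p_b, lower.tail = FALSE),
                p_null = p_b)
  }
  structure(list(
    n_trials = n, k_coincident = k, p_a_hat = p_a, p_b_hat = p_b,
    p_null = res$p_null, p_value = res$p_value,
    shared = res$p_value < alpha, alpha = alpha, mode = mode,
    experiment_id = outcomes$experiment_id, animal_id = outcomes$animal_id
  ), class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf(
    "<coincidence_result> %s: k = %d / %d trials (p_a = %.2f, p_b = %.2f), %s-null p = %.4g -> %s\n",
    x$experiment_id, x$k_coincident, x$n_trials, x$p_a_hat, x$p_b_hat,
    x$mode, x$p_value, if (x$shared) "shared axon" else "not shared"))
  invisible(x)
}

#' Summarise shared-axon classifications across two groups
#'
#' Tabulates shared/not-shared classifications per group, forms the 2x2
#' contingency table (rows = groups in the order given, columns = shared,
#' not shared) and attaches Barnard's unconditional exact test on the group
#' proportions.
#'
#' @param group_results Named list of two lists of `coincidence_result`
#'   objects (one list per group).
#' @param ... Passed to [barnard_exact()] (e.g. `alternative`, `grid_step`).
#' @return List with `per_group` (data frame: group, n_shared, n_experiments,
#'   proportion), `table` (2x2 matrix) and `barnard` (a `barnard_result`).
#' @export
summarize_connectivity <- function(group_results, ...) {
  if (length(group_results) != 2L || is.null(names(group_results)))
    abort_data("supply a named list of exactly two groups of coincidence results")
  for (g in names(group_results))
    if (length(group_results[[g]]) < 1L)
      abort_insufficient(sprintf("group '%s' has no experiments", g))
  shared <- vapply(group_results, function(rs)
    sum(vapply(rs, `[[`, logical(1), "shared")), integer(1))
  n <- vapply(group_results, length, integer(1))
  tab <- cbind(shared = shared, not_shared = n - shared)
  rownames(tab) <- names(group_results)
  list(
    per_group = data.frame(group = names(group_results),
                           n_shared = as.integer(shared),
                           n_experiments = as.integer(n),
                           proportion = shared / n,
                           row.names = NULL),
    table = tab,
    barnard = barnard_exact(tab, ...)
  )
}
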