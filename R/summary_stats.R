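# Group-comparison statistics ---------------------------------------------------
#
# Group tests operate either on raw per-animal values or on printed summary
# triplets (mean, SEM, N). Because published summaries are rounded, p-values
# recomputed from them agree with published values only to printed precision.

#' A (mean, SEM, N) group summary
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Number of animals (>= 2).
#' @return A `group_summary` object.
#' @export
group_summary <- function(mean, sem, n) {
  if (!is.finite(mean)) abort_data("mean must be finite")
  if (!is.finite(sem) || sem < 0) abort_data("sem must be >= 0")
  if (!is.numeric(n) || n < 2 || n != round(n))
    abort_data("n must be an integer >= 2")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Summarise raw values into a (mean, SEM, N) triplet
#'
#' @param x Numeric vector of per-animal values.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) abort_data("need at least two finite values")
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Unpaired t-test from summary statistics
#'
#' Reconstructs group SDs as `sem * sqrt(n)`. The pooled variant uses the
#' pooled variance with `n1 + n2 - 2` degrees of freedom; the Welch variant
#' uses `SE = sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite degrees of
#' freedom. Equivalent to the corresponding raw-data t-test when the
#' summaries are exact.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A `t_test_result`: list with `t`, `df`, `p_two_tailed`, `variant`.
#' @export
t_from_summary <- function(g1, g2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  for (g in list(g1, g2))
    if (!inherits(g, "group_summary")) abort_data("g1 and g2 must be group summaries")
  if (variant == "welch") {
    se2 <- g1$sem^2 + g2$sem^2
    if (se2 <= 0) abort_data("both groups have zero SEM: t is undefined")
    t <- (g1$mean - g2$mean) / sqrt(se2)
    df <- se2^2 / (g1$sem^4 / (g1$n - 1) + g2$sem^4 / (g2$n - 1))
  } else {
    v1 <- g1$sem^2 * g1$n
    v2 <- g2$sem^2 * g2$n
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * v1 + (g2$n - 1) * v2) / df
    if (sp2 <= 0) abort_data("zero pooled variance: t is undefined")
    t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  }
  structure(list(t = t, df = df,
                 p_two_tailed = 2 * stats::pt(-abs(t), df),
                 variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> %s t = %.4f, df = %.2f, two-tailed p = %.4g\n",
              x$variant, x$t, x$df, x$p_two_tailed))
  invisible(x)
}

#' Unpaired t-test on raw per-animal values
#'
#' @param x,y Numeric vectors.
#' @param variant `"welch"` or `"pooled"`.
#' @return A `t_test_result`.
#' @export
t_raw <- function(x, y, variant = c("welch", "pooled")) {
  t_from_summary(summarize_group(x), summarize_group(y), variant)
}

#' Paired t-test
#'
#' @param values_a,values_b Equal-length numeric vectors (e.g. control and
#'   drug amplitudes per animal).
#' @return A `t_test_result` with `variant = "paired"`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    abort_data("paired samples must have equal length")
  if (length(values_a) < 2L) abort_data("need at least two pairs")
  d <- values_a - values_b
  sd_d <- stats::sd(d)
  n <- length(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    # identical pairs carry no evidence of an effect; a constant non-zero
    # shift makes t formally infinite and is reported as degenerate data
    if (all(d == 0))
      return(structure(list(t = 0, df = n - 1, p_two_tailed = 1,
                            variant = "paired"), class = "t_test_result"))
    abort_data("zero variance of paired differences: t is degenerate")
  }
  t <- mean(d) / (sd_d / sqrt(n))
  structure(list(t = t, df = n - 1,
                 p_two_tailed = 2 * stats::pt(-abs(t), n - 1),
                 variant = "paired"),
            class = "t_test_result")
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. `u_statistic` is the number of
#' (x, y) pairs with x > y (ties counted 1/2). For samples with both sizes
#' <= `exact_max` and no ties the exact null distribution is used; otherwise
#' a tie-corrected normal approximation (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return An `mwu_result`: list with `u_statistic`, `p_two_tailed`,
#'   `method` (`"exact"` or `"normal-approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) < 1L || length(y) < 1L)
    abort_data("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    # exact two-sided p: double the smaller tail of the null U distribution
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    method <- "exact"
  } else {
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal-approx"
  }
  structure(list(u_statistic = u, p_two_tailed = min(p, 1), method = method),
            class = "mwu_result")
}
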