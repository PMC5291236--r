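# Barnard's unconditional exact test ------------------------------------------
#
# Exact unconditional test for a 2x2 table with fixed row totals (rows =
# groups, columns = outcome). The observed statistic is the pooled-variance
# Wald score on the difference of the two group proportions; the p-value is
# the supremum, over the nuisance common success probability pi, of the total
# probability of all outcome tables at least as extreme as the one observed.
# The supremum is taken on a regular grid plus a local continuous refinement
# around the best grid point, so refining the grid cannot increase the
# reported p beyond numerical tolerance.

barnard_statistic <- function(x1, x2, n1, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  t <- (p1 - p2) / se
  t[!is.finite(t)] <- 0  # zero pooled variance (all-0 or all-1 tables)
  t
}

#' Barnard's exact unconditional test for a 2x2 table
#'
#' @param table 2x2 matrix of counts, rows = groups (e.g. genotypes), columns
#'   = outcome (e.g. shared / not shared). Row totals are treated as fixed
#'   sample sizes.
#' @param alternative `"two.sided"` (extremeness by absolute value of the
#'   pooled Wald score), `"greater"` (group 1 proportion larger) or
#'   `"less"`.
#' @param grid_step Nuisance-parameter grid step (default 0.001).
#' @param refine Logical: run a continuous local optimisation around the best
#'   grid point (default TRUE).
#' @return A `barnard_result`: list with `p_value`, `statistic_observed`,
#'   `nuisance_at_max`, `grid_step`, `alternative`,
#'   `variant = "wald_pooled"` and the input `table`.
#' @export
barnard_exact <- function(table, alternative = c("two.sided", "greater", "less"),
                          grid_step = 0.001, refine = TRUE) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    abort_data("Barnard test requires a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    abort_data("table counts must be non-negative integers")
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (n1 < 1 || n2 < 1) abort_data("both row totals must be >= 1")
  check_pos(grid_step, "grid_step")

  a <- table[1, 1]; c_ <- table[2, 1]
  x1 <- rep(0:n1, each = n2 + 1)
  x2 <- rep(0:n2, times = n1 + 1)
  T <- barnard_statistic(x1, x2, n1, n2)
  T0 <- barnard_statistic(a, c_, n1, n2)
  tol <- 1e-10
  region <- switch(alternative,
    two.sided = abs(T) >= abs(T0) - tol,
    greater = T >= T0 - tol,
    less = T <= T0 + tol
  )
  lpr <- lchoose(n1, x1) + lchoose(n2, x2)
  k <- (x1 + x2)[region]
  m <- (n1 + n2) - k
  lp <- lpr[region]
  # pi is always interior (the grid and refinement interval exclude 0 and 1;
  # the tail probability extends continuously to 0 at the endpoints unless
  # the degenerate table is in the region, in which case interior values
  # approach that limit anyway)
  tail_prob <- function(pi) sum(exp(lp + k * log(pi) + m * log1p(-pi)))
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  pv <- vapply(grid, tail_prob, numeric(1))
  i_max <- which.max(pv)
  p <- pv[i_max]
  pi_max <- grid[i_max]
  if (refine) {
    lo <- max(1e-9, pi_max - grid_step)
    hi <- min(1 - 1e-9, pi_max + grid_step)
    opt <- stats::optimize(tail_prob, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    if (opt$objective > p) {
      p <- opt$objective
      pi_max <- opt$maximum
    }
  }
  structure(list(
    p_value = min(p, 1),
    statistic_observed = T0,
    nuisance_at_max = pi_max,
    grid_step = grid_step,
    alternative = alternative,
    variant = "wald_pooled",
    table = table
  ), class = "barnard_result")
}

#' @export
print.barnard_result <- function(x, ...) {
  cat(sprintf(
    "<barnard_result> pooled-Wald score = %.4f, %s p = %.4g (nuisance pi* = %.4f)\n",
    x$statistic_observed, x$alternative, x$p_value, x$nuisance_at_max))
  invisible(x)
}
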