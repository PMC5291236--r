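# Independent oracles used across the suite. Each is deliberately coded by a
# different route than the implementation it checks.

# Upper-tail binomial probability P(K >= k) by direct term summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Brute-force Barnard: enumerate every outcome table on a plain fine nuisance
# grid (no refinement), table probabilities via dbinom products.
barnard_oracle <- function(tab, alternative = "two.sided", grid = NULL) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  if (is.null(grid)) grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  wald <- function(x1, x2) {
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    t <- (p1 - p2) / se
    ifelse(is.finite(t), t, 0)
  }
  g <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  T <- wald(g$x1, g$x2)
  T0 <- wald(tab[1, 1], tab[2, 1])
  keep <- switch(alternative,
                 two.sided = abs(T) >= abs(T0) - 1e-10,
                 greater = T >= T0 - 1e-10,
                 less = T <= T0 + 1e-10)
  x1 <- g$x1[keep]; x2 <- g$x2[keep]
  per_table <- vapply(seq_along(x1), function(i)
    dbinom(x1[i], n1, grid) * dbinom(x2[i], n2, grid),
    numeric(length(grid)))
  max(rowSums(per_table))
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(idx) sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# Short synthetic sweep config used where full-length traces are unnecessary.
quick_epsc_config <- function(...) {
  epsc_gen_config(pre_ms = 5, post_ms = 25, ...)
}
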