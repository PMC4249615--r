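# Independent oracles used across the suite. These deliberately use the
# most naive correct formulation available so they cannot share a defect
# with the implementation they check.

# Plug-in discrete MI (nats) from the joint frequency table.
plugin_discrete_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- tab[i, j]
    if (p > 0) s <- s + p * log(p / (px[i] * py[j]))
  }
  s
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  # step-up: running minimum from the largest rank downwards
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability P(X >= k) by direct summation.
hyper_upper <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two sample groups with group-specific mean profiles (correlation-visible
# separation), probes x samples.
two_group_matrix <- function(n_probes, n1, n2, shift_sd = 3, seed = 1) {
  set.seed(seed)
  mu1 <- rnorm(n_probes, sd = shift_sd)
  mu2 <- rnorm(n_probes, sd = shift_sd)
  m <- cbind(matrix(mu1 + rnorm(n_probes * n1), n_probes, n1),
             matrix(mu2 + rnorm(n_probes * n2), n_probes, n2))
  dimnames(m) <- list(sprintf("p%03d", seq_len(n_probes)),
                      sprintf("s%03d", seq_len(n1 + n2)))
  expr_cohort(m, labels = rep(c("PM", "APL"), c(n1, n2)))
}
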