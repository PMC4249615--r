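# Shared fixtures. The scaled-down generator configuration keeps unit tests
# fast; acceptance tests use the package defaults.

small_config <- function(seed = 1, ...) {
  args <- list(n_seed_anchors = 20, members_per_anchor = 4,
               n_background_genes = 60, n_uninformative_genes = 80,
               samples_a = c(M0 = 8, M1 = 15, M2 = 15, M3 = 12,
                             M4 = 15, M5 = 10),
               samples_b = c(M0 = 8, M1 = 12, M2 = 14, M3 = 11,
                             M4 = 13, M5 = 10),
               apl_up_size = 12, apl_down_size = 24,
               apl_shift = 2,    # extra power for the small M3 groups
               seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# Pipeline call with settings scaled to the small cohorts (looser edge
# threshold for the smaller sample sizes, like the full-cohort analysis
# loosens its threshold for the smaller of its two cohorts, and a smaller
# component-size rule for the smaller planted modules).
small_pipeline <- function(sim, rng_seed, ...) {
  run_consensus_pipeline(sim$cohort_a, sim$cohort_b, sim$annotation,
                         sim$seed_genes, rng_seed = rng_seed,
                         p_threshold_a = 1e-4, p_threshold_b = 1e-4,
                         min_component_genes = 5, calib_pairs = 400, ...)
}

# A labeled cohort of independent probes on the raw-intensity scale.
null_cohort <- function(n_probes, n_samples, seed = 1, labels = NULL) {
  set.seed(seed)
  m <- matrix(2^(rnorm(n_probes * n_samples) + 8), n_probes, n_samples,
              dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expr_cohort(m, labels = labels)
}

# Centered log-scale cohort (already normalized), independent probes.
null_normalized <- function(n_probes, n_samples, seed = 1, labels = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m <- m - rowMeans(m)
  expr_cohort(m, labels = labels)
}

# Planted chain X -> Y -> Z (no direct X-Z term), returned as a normalized
# 3-probe cohort.
chain_cohort <- function(n = 200, beta = 1, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta * x + rnorm(n, sd = noise_sd)
  z <- beta * y + rnorm(n, sd = noise_sd)
  m <- rbind(X = x, Y = y, Z = z)
  colnames(m) <- sprintf("s%03d", seq_len(n))
  expr_cohort(m - rowMeans(m))
}

# Minimal hand-built mi_network via the exported inference path is overkill
# for topology-only tests; build the object through the package constructor.
edges_network <- function(df, seeds = character()) {
  aplnet:::mi_network(df, seed_probes = seeds)
}
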