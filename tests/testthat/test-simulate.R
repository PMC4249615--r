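test_that("generation is deterministic under config + seed", {
  cfg <- small_config(seed = 5)
  s1 <- generate_cohorts(cfg)
  s2 <- generate_cohorts(cfg)
  expect_identical(s1$cohort_a$values, s2$cohort_a$values)
  expect_identical(s1$cohort_b$values, s2$cohort_b$values)
  expect_identical(s1$truth$edges, s2$truth$edges)
  # a different seed changes values but not structure sizes
  s3 <- generate_cohorts(small_config(seed = 6))
  expect_false(identical(s1$cohort_a$values, s3$cohort_a$values))
  expect_identical(dim(s1$cohort_a$values), dim(s3$cohort_a$values))
  expect_identical(nrow(s1$truth$edges), nrow(s3$truth$edges))
})

test_that("dimensions follow the configuration", {
  cfg <- small_config(seed = 9)
  sim <- generate_cohorts(cfg)
  expect_equal(ncol(sim$cohort_a$values), sum(cfg$samples_a))
  expect_equal(ncol(sim$cohort_b$values), sum(cfg$samples_b))
  n_genes <- cfg$n_seed_anchors + (cfg$apl_up_size - 1) +
    (cfg$apl_down_size - cfg$n_down_anchors) +
    (cfg$n_seed_anchors - 1 - cfg$n_down_anchors) * cfg$members_per_anchor +
    cfg$n_background_genes + cfg$n_uninformative_genes
  expect_equal(length(unique(sim$truth$annotation)), n_genes)
  expect_length(sim$seed_genes, cfg$n_seed_anchors)
  # every gene keeps at least one probe in the shared (intersectable) set
  shared <- intersect(probe_ids(sim$cohort_a), probe_ids(sim$cohort_b))
  expect_setequal(unique(sim$truth$annotation[shared]),
                  unique(sim$truth$annotation))
  expect_error(generate_cohorts(
    small_config(seed = 1, apl_down_size = 2)), "module sizes")
})

test_that("planted M3 shift is recovered empirically", {
  cfg <- generator_config(seed = 13,
                          samples_a = c(M1 = 100, M3 = 20),
                          samples_b = c(M1 = 20, M3 = 5))
  sim <- generate_cohorts(cfg)
  norm <- intersect_and_normalize(sim$cohort_a, sim$cohort_b)
  up_probes <- intersect(
    names(sim$annotation)[sim$annotation %in% sim$truth$modules$apl_up],
    probe_ids(norm$a))
  m3 <- norm$a$labels == "M3"
  # treat samples as the sampling units: probes share gene-level draws,
  # so averaging over probes first gives the honest standard error
  prof <- colMeans(norm$a$values[up_probes, ])
  diff <- mean(prof[m3]) - mean(prof[!m3])
  se <- sqrt(var(prof[m3]) / sum(m3) + var(prof[!m3]) / sum(!m3))
  expect_lt(abs(diff - cfg$apl_shift), 3 * se)
})

test_that("regulator miRNAs anti-correlate with their targets", {
  cfg <- small_config(seed = 21,
                      samples_a = c(M0 = 20, M1 = 30, M2 = 25, M3 = 20,
                                    M4 = 25, M5 = 20))   # n = 140
  sim <- generate_cohorts(cfg)
  mir <- generate_mirnas(cfg, sim$truth, sim$cohort_a)
  expect_identical(sample_ids(mir), sample_ids(sim$cohort_a))
  norm <- log2(sim$cohort_a$values)
  norm <- norm - rowMeans(norm)
  targets <- intersect(
    names(sim$annotation)[sim$annotation %in% sim$truth$modules$apl_down],
    rownames(norm))
  r <- cor(mir$values["miR-R01", ], t(norm[targets, ]))
  expect_gte(mean(r < -0.4), 0.8)
  # decoys show at most a small tail beyond the same threshold
  rd <- cor(mir$values["miR-D01", ], t(norm[targets, ]))
  expect_lte(mean(rd < -0.4), 0.05)
  # determinism
  mir2 <- generate_mirnas(cfg, sim$truth, sim$cohort_a)
  expect_identical(mir$values, mir2$values)
})

test_that("time courses relax planted shifts toward baseline", {
  cfg <- small_config(seed = 25)
  sim <- generate_cohorts(cfg)
  tc <- generate_timecourse(cfg, sim$truth, timepoints = c(0, 12, 72, 96),
                            tau = 12, noise_sd = 0)
  expect_true(all(tc$values[, "0"] == 0))
  up <- sim$truth$modules$apl_up
  # at t = 6*tau the remaining shift is below 0.25% of the initial one
  expect_lt(max(abs(tc$values[up, "72"] + cfg$apl_shift)),
            cfg$apl_shift * 0.0025 + 1e-9)
  expect_error(generate_timecourse(cfg, sim$truth, tau = -1), "tau")
  expect_error(generate_timecourse(cfg, sim$truth, timepoints = c(6, 12)),
               "start at 0")
})

test_that("recovery metrics count planted, indirect and missing edges", {
  cfg <- small_config(seed = 29)
  sim <- generate_cohorts(cfg)
  truth <- sim$truth
  probe_of <- function(g) names(truth$annotation)[truth$annotation == g][1]
  # perfect reconstruction at probe level
  perfect <- edges_network(data.frame(
    from = vapply(truth$edges$gene_a, probe_of, ""),
    to = vapply(truth$edges$gene_b, probe_of, ""),
    mi = 0.5, p = 1e-9))
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # disjoint reconstruction
  bg <- truth$modules$background[1:4]
  wrong <- edges_network(data.frame(
    from = vapply(bg[1:2], probe_of, ""),
    to = vapply(bg[3:4], probe_of, ""), mi = 0.5, p = 1e-9))
  ev0 <- evaluate_recovery(wrong, truth)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  # indirect pairs: counted against precision unless DPI was disabled
  mem <- truth$catalogue[truth$catalogue$role == "member", ]
  sib <- mem[mem$anchor == mem$anchor[1], ][1:2, ]
  mixed <- edges_network(data.frame(
    from = c(probe_of(sib$anchor[1]), probe_of(sib$gene[1])),
    to = c(probe_of(sib$gene[1]), probe_of(sib$gene[2])),
    mi = 0.5, p = 1e-9))
  ev1 <- evaluate_recovery(mixed, truth, dpi_applied = TRUE)
  expect_equal(ev1$precision, 0.5)
  ev2 <- evaluate_recovery(mixed, truth, dpi_applied = FALSE)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$n_indirect_recovered, 1)
})

test_that("generator-induced correlation matches the Gaussian closed form", {
  cfg <- generator_config(seed = 33, sigma_probe = 0,
                          samples_a = c(M1 = 2000, M3 = 2),
                          samples_b = c(M1 = 8, M3 = 2),
                          probes_per_gene = c(1, 1))
  sim <- generate_cohorts(cfg)
  ann <- sim$annotation
  mem <- sim$truth$catalogue[sim$truth$catalogue$role == "member", ]
  mem <- mem[mem$module == "none", ][1, ]
  v <- log2(sim$cohort_a$values)
  v <- v - rowMeans(v)
  keep <- sim$cohort_a$labels == "M1"
  x <- v[names(ann)[ann == mem$gene][1], keep]
  y <- v[names(ann)[ann == mem$anchor][1], keep]
  rho <- cfg$beta / sqrt(cfg$beta^2 + cfg$sigma_gene^2)
  expect_lt(abs(estimate_mi(x, y) - (-0.5 * log(1 - rho^2))), 0.1)
})
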