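test_that("a planted star is fully recovered in seed-restricted mode", {
  set.seed(17)
  n <- 200
  anchor <- rnorm(n)
  members <- sapply(1:10, function(i) anchor + rnorm(n, sd = 0.3))
  m <- rbind(t(cbind(anchor, members)),
             matrix(rnorm(60 * n), 60, n))
  rownames(m) <- c("seed1", sprintf("m%02d", 1:10), sprintf("bg%02d", 1:60))
  colnames(m) <- sprintf("s%03d", 1:n)
  co <- expr_cohort(m - rowMeans(m))
  calib <- calibrate_null(co, n_pairs = 500, rng_seed = 3)
  ann <- setNames(rownames(m), rownames(m))
  seeds <- resolve_seeds("seed1", ann, co)
  net <- infer_relevance_network(co, seeds, 1e-5, calib)
  got <- net$edges
  star <- paste(pmin(got$from, got$to), pmax(got$from, got$to)) |>
    intersect(paste(pmin("seed1", sprintf("m%02d", 1:10)),
                    pmax("seed1", sprintf("m%02d", 1:10))))
  expect_length(star, 10)
  expect_true(all(net$edges$from != net$edges$to))
  expect_false(any(duplicated(paste(pmin(got$from, got$to),
                                    pmax(got$from, got$to)))))
  expect_true(net$is_seed[["seed1"]])
})

test_that("independent data give at most one spurious edge at p < 1e-15", {
  co <- null_normalized(200, 100, seed = 23)
  calib <- calibrate_null(co, n_pairs = 500, rng_seed = 5)
  ann <- setNames(probe_ids(co), probe_ids(co))
  seeds <- resolve_seeds(probe_ids(co)[1:20], ann, co)
  net <- suppressWarnings(
    infer_relevance_network(co, seeds, 1e-15, calib))
  expect_lte(nrow(net$edges), 1)
})

test_that("DPI removes the weakest triangle edge and honors tolerance", {
  tri <- data.frame(from = c("X", "Y", "X"), to = c("Y", "Z", "Z"),
                    mi = c(0.8, 0.7, 0.3), p = c(1e-9, 1e-8, 1e-6))
  pruned <- apply_dpi(edges_network(tri), tolerance = 0)
  expect_identical(sort(paste(pruned$edges$from, pruned$edges$to)),
                   c("X Y", "Y Z"))
  tri2 <- tri
  tri2$mi[3] <- 0.69
  kept <- apply_dpi(edges_network(tri2), tolerance = 0.1)
  expect_equal(nrow(kept$edges), 3)   # 0.69 >= 0.9 * 0.7
  # triangle-free graphs pass through unchanged
  path <- data.frame(from = c("A", "B"), to = c("B", "C"),
                     mi = c(0.5, 0.1), p = c(1e-8, 1e-4))
  expect_equal(nrow(apply_dpi(edges_network(path), 0)$edges), 2)
})

test_that("DPI output is a subgraph and idempotent at tolerance 0", {
  set.seed(31)
  n_nodes <- 30
  cmb <- combn(n_nodes, 2)
  pick <- sample(ncol(cmb), 120, replace = FALSE)
  e <- data.frame(from = sprintf("n%02d", cmb[1, pick]),
                  to = sprintf("n%02d", cmb[2, pick]),
                  mi = runif(120, 0.05, 1), p = 1e-8)
  net <- edges_network(e)
  p1 <- apply_dpi(net, 0)
  key <- function(x) paste(x$edges$from, x$edges$to)
  expect_true(all(key(p1) %in% key(net)))
  p2 <- apply_dpi(p1, 0)
  expect_identical(key(p2), key(p1))
})

test_that("DPI prunes the indirect edge of planted chains", {
  calib <- calibrate_null(null_normalized(60, 200, seed = 40),
                          n_pairs = 300, rng_seed = 41)
  removed <- detected <- 0
  for (s in 1:40) {
    co <- chain_cohort(n = 200, seed = 1000 + s)
    ann <- setNames(probe_ids(co), probe_ids(co))
    seeds <- resolve_seeds("X", ann, co)
    net <- infer_relevance_network(co, seeds, 1e-4, calib,
                                   mode = "all_pairs")
    if (nrow(net$edges) == 3) {
      detected <- detected + 1
      pruned <- apply_dpi(net, 0)
      k <- paste(pruned$edges$from, pruned$edges$to)
      if (!("X Z" %in% k) && length(k) == 2) removed <- removed + 1
    }
  }
  expect_gt(detected, 30)
  expect_gte(removed / detected, 0.95)
})

test_that("consensus keeps exactly the shared unordered edges", {
  na <- edges_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                 mi = c(0.5, 0.4), p = c(1e-9, 1e-8)))
  nb <- edges_network(data.frame(from = c("C", "C"), to = c("B", "D"),
                                 mi = c(0.45, 0.3), p = c(1e-7, 1e-6)))
  cons <- consensus_edges(na, nb)
  expect_equal(nrow(cons$edges), 1)
  expect_identical(cons$edges$from, "B")
  expect_identical(cons$edges$to, "C")
  expect_equal(cons$edges$mi_a, 0.4)
  expect_equal(cons$edges$mi_b, 0.45)
  # commutative up to attribute naming, and always a subset
  rev <- consensus_edges(nb, na)
  expect_identical(paste(rev$edges$from, rev$edges$to),
                   paste(cons$edges$from, cons$edges$to))
  expect_lte(nrow(cons$edges), min(2, 2))
})

test_that("modules are connected components with deterministic labels", {
  e <- data.frame(from = c("a1", "a2", "a3", "b1", "b2", "b3"),
                  to   = c("a2", "a3", "a1", "b2", "b3", "b1"),
                  mi = 0.5, p = 1e-9)
  mod <- detect_modules(edges_network(e))
  expect_equal(nrow(mod$sizes), 2)
  expect_equal(mod$sizes$n_probes, c(3L, 3L))
  expect_equal(sum(mod$sizes$n_probes), 6L)
  # ties by smallest node id: the "a" triangle is component 1
  expect_equal(unname(mod$membership[c("a1", "b1")]), c(1L, 2L))
})
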