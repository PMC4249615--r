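test_that("intersection restricts both cohorts to shared probes in order", {
  ma <- matrix(2^c(1:12), 3, 4,
               dimnames = list(c("A", "B", "C"), paste0("a", 1:4)))
  mb <- matrix(2^c(1:12), 3, 4,
               dimnames = list(c("B", "C", "D"), paste0("b", 1:4)))
  out <- intersect_and_normalize(expr_cohort(ma), expr_cohort(mb))
  expect_identical(rownames(out$a$values), c("B", "C"))
  expect_identical(rownames(out$b$values), c("B", "C"))
  mc <- matrix(2^c(1:4), 2, 2, dimnames = list(c("X", "Y"), paste0("c", 1:2)))
  expect_error(intersect_and_normalize(expr_cohort(ma), expr_cohort(mc)),
               "common")
})

test_that("normalization is log2 then mean-centering", {
  m <- matrix(c(1, 2, 4, 8,
                5, 5, 5, 5), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:4)))
  out <- intersect_and_normalize(expr_cohort(m), expr_cohort(m))
  expect_equal(unname(out$a$values["A", ]), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(unname(out$a$values["B", ]), rep(0, 4))
  expect_true(all(abs(rowMeans(out$a$values)) < 1e-9))
  m[1, 2] <- 0
  expect_error(intersect_and_normalize(expr_cohort(m), expr_cohort(m)),
               "non-positive.*'A'.*'s2'")
})

test_that("entropy filter removes the constant probe and respects ties", {
  set.seed(3)
  m <- matrix(rnorm(10 * 40), 10, 40,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%02d", 1:40)))
  m[4, ] <- 0                      # constant: entropy 0, unique minimum
  co <- expr_cohort(m)
  filt <- entropy_filter(co, percentile = 10)
  expect_false("p04" %in% rownames(filt$values))
  expect_equal(nrow(filt$values), 9)
  # survivors keep input order
  expect_identical(rownames(filt$values), setdiff(rownames(m), "p04"))

  # identical value-distributions => equal entropies => strict cut keeps all
  m2 <- matrix(rep(rnorm(30), each = 8), 8, 30, byrow = FALSE,
               dimnames = list(paste0("q", 1:8), paste0("s", 1:30)))
  filt2 <- entropy_filter(expr_cohort(m2), percentile = 10)
  expect_equal(nrow(filt2$values), 8)

  expect_error(entropy_filter(expr_cohort(m[, 1, drop = FALSE])), "2 samples")
})

test_that("uniform histograms have higher entropy than concentrated ones", {
  n <- 49                                  # 7 bins
  spread <- seq(0, 1, length.out = n)      # near-uniform over bins
  lump <- c(rep(0.5, n - 1), 1)            # almost all mass in one bin
  expect_gt(probe_entropy(spread), probe_entropy(lump))
})

test_that("a second entropy pass with the recorded cutoff removes nothing", {
  set.seed(9)
  co <- null_normalized(50, 30)
  f1 <- entropy_filter(co, percentile = 10)
  f2 <- entropy_filter(f1, cutoff = attr(f1, "entropy_cutoff"))
  expect_identical(rownames(f2$values), rownames(f1$values))
})

test_that("differential prefilter keeps separated probes and drops flat ones", {
  set.seed(11)
  n1 <- 20; n2 <- 20
  labels <- rep(c("M3", "M1"), c(n1, n2))
  m <- matrix(rnorm(30 * 40, sd = 0.5), 30, 40,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:40)))
  m[1, labels == "M3"] <- m[1, labels == "M3"] + 2      # strong shift, sd 0.5
  m[2, ] <- rep(c(1, 2), 20)                            # identical groups
  m[2, labels == "M3"] <- m[2, labels == "M1"]
  co <- expr_cohort(m - rowMeans(m), labels = labels)
  kept <- prefilter_transcripts(co, "M3", alpha = 0.05)
  expect_true("p01" %in% rownames(kept$values))
  expect_false("p02" %in% rownames(kept$values))
  # oracle: the same call decided by stats::t.test p-values + p.adjust
  pvals <- apply(co$values, 1, function(v)
    stats::t.test(v[labels == "M3"], v[labels == "M1"])$p.value)
  qvals <- p.adjust(pvals, "BH")
  expect_identical(rownames(kept$values), names(qvals)[qvals < 0.05])
})

test_that("prefilter and entropy filter compose as survivor-set intersection", {
  # Composition is exact when the differential decision is evaluated on the
  # same probe universe for both sides; the BH correction makes the decision
  # set-dependent, so the single-filter survivor set is computed on the
  # entropy-filtered universe here.
  set.seed(21)
  labels <- rep(c("M3", "M2"), c(10, 14))
  co <- null_normalized(60, 24, seed = 21, labels = labels)
  co$values[1:6, labels == "M3"] <- co$values[1:6, labels == "M3"] + 3
  ef <- entropy_filter(co, percentile = 10)
  both <- prefilter_transcripts(ef, "M3")
  de_on_ef <- differential_expression(ef, "M3")
  pf_survivors <- de_on_ef$probe[de_on_ef$q < 0.05]
  expect_identical(rownames(both$values),
                   intersect(rownames(ef$values), pf_survivors))
  # and both orders only ever shrink the probe set, preserving order
  expect_true(all(rownames(both$values) %in% rownames(co$values)))
  expect_false(is.unsorted(match(rownames(both$values),
                                 rownames(co$values))))
})

test_that("TSV readers enforce the documented dialects", {
  d <- withr::local_tempdir()
  ep <- file.path(d, "expr.tsv")
  writeLines(c("probe_id\ts1\ts2", "pA\t1.5\t2.5", "pB\t3\t4"), ep)
  co <- read_expression_tsv(ep)
  expect_equal(dim(co$values), c(2L, 2L))
  writeLines(c("probe_id\ts1\ts2", "pA\t1.5\tNA"), ep)
  expect_error(read_expression_tsv(ep), "missing value.*'pA'.*'s2'")

  sp <- file.path(d, "seeds.txt")
  writeLines(c("# seed genes", "TP53", "VEGFA  ", "", "HK2 # glycolysis"), sp)
  expect_identical(read_seed_list(sp), c("TP53", "VEGFA", "HK2"))

  ap <- file.path(d, "ann.tsv")
  writeLines(c("pA\tTP53", "pB\tTP53", "pC\tHK2"), ap)
  ann <- read_annotation_tsv(ap)
  expect_identical(unname(ann[c("pA", "pB", "pC")]), c("TP53", "TP53", "HK2"))
})
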