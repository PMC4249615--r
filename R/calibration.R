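#' Calibrate the null distribution of mutual information
#'
#' Draws random probe pairs from a cohort, destroys any dependence by
#' permuting one member of each pair, estimates MI for each permuted pair,
#' and fits the log of the empirical survival function against MI over the
#' upper tail by least squares: `ln P(MI > m) ~ a + b m` with `b < 0`.
#' The fitted tail converts MI values to edge p-values and significance
#' thresholds, including extrapolation far beyond the permutation resolution
#' (thresholds like 1e-15 exceed any feasible permutation count).
#'
#' @param cohort a normalized [expr_cohort()].
#' @param n_pairs number of permuted pairs to draw (>= 200); default 1000.
#' @param rng_seed integer seed for pair sampling and permutation.
#' @param tail_fraction upper fraction of the MI sample used in the fit;
#'   default 0.10.
#' @param min_split,alpha_split estimator controls, see [estimate_mi()].
#' @return An object of class `mi_null_calibration` with elements `a`, `b`
#'   (fit coefficients), `samples` (permuted MI values), `rng_seed`,
#'   `n_pairs`, `n_samples`, `tail_fraction`.
#' @seealso [mi_pvalue()], [mi_threshold()]
#' @export
calibrate_null <- function(cohort, n_pairs = 1000, rng_seed = 1,
                           tail_fraction = 0.10,
                           min_split = 8, alpha_split = 0.05) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (n_pairs < 200) stop("need at least 200 permutation pairs")
  v <- cohort$values
  np <- nrow(v)
  n <- ncol(v)
  if (np < 2) stop("need at least 2 probes")
  set.seed(rng_seed %% .Machine$integer.max)
  i <- sample.int(np, n_pairs, replace = TRUE)
  j <- sample.int(np, n_pairs, replace = TRUE)
  fix <- which(i == j)
  while (length(fix)) {
    j[fix] <- sample.int(np, length(fix), replace = TRUE)
    fix <- fix[i[fix] == j[fix]]
  }
  chi_crit <- stats::qchisq(1 - alpha_split, df = 3)
  ranks <- rank_rows(v[sort(unique(c(i, j))), , drop = FALSE])
  row_of <- stats::setNames(seq_len(nrow(ranks)), rownames(ranks))
  ri <- row_of[rownames(v)[i]]
  rj <- row_of[rownames(v)[j]]
  mis <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    perm <- sample.int(n)
    mis[k] <- .mi_ranks_cpp(ranks[ri[k], ], ranks[rj[k], perm],
                            as.integer(min_split), chi_crit)
  }
  ord <- sort(mis)
  surv <- 1 - (seq_len(n_pairs) - 0.5) / n_pairs  # midpoint survival estimate
  tail_n <- max(20L, ceiling(tail_fraction * n_pairs))
  idx <- seq(n_pairs - tail_n + 1L, n_pairs)
  fit <- stats::lm(log(surv[idx]) ~ ord[idx])
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b >= 0)
    stop("degenerate null tail fit (b >= 0); increase n_pairs")
  structure(list(a = a, b = b, samples = mis, rng_seed = rng_seed,
                 n_pairs = n_pairs, n_samples = n,
                 tail_fraction = tail_fraction),
            class = "mi_null_calibration")
}

#' @export
print.mi_null_calibration <- function(x, ...) {
  cat(sprintf(
    "<mi_null_calibration> n_pairs=%d n_samples=%d seed=%d\n  ln P(MI>m) ~ %.3f %+.3f m ; threshold(p=1e-5) = %.4f nats\n",
    x$n_pairs, x$n_samples, x$rng_seed, x$a, x$b, mi_threshold(x, 1e-5)))
  invisible(x)
}

#' Edge p-value from a calibrated null
#'
#' @param calib an [calibrate_null()] result.
#' @param mi MI value(s) in nats.
#' @return `min(1, exp(a + b * mi))`, vectorized.
#' @export
mi_pvalue <- function(calib, mi) {
  stopifnot(inherits(calib, "mi_null_calibration"))
  pmin(1, exp(calib$a + calib$b * mi))
}

#' MI threshold achieving a target edge p-value
#'
#' Inverse of [mi_pvalue()]: strictly decreasing in `p`.
#' @param calib an [calibrate_null()] result.
#' @param p target p-value(s) in (0, 1).
#' @return MI threshold(s) in nats.
#' @export
mi_threshold <- function(calib, p) {
  stopifnot(inherits(calib, "mi_null_calibration"))
  (log(p) - calib$a) / calib$b
}
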