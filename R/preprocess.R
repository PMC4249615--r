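#' Harmonize two cohorts to their shared probes and normalize
#'
#' Restricts both cohorts to the probe sets measured on both platforms (in
#' identical order), then normalizes each cohort independently: every probe
#' row is log2-transformed and mean-centered across that cohort's samples —
#' i.e. each value becomes the log2 ratio to the probe's geometric mean.
#' Centering-before-log is not defined for non-positive intensities, so the
#' log transform always comes first.
#'
#' @param cohort_a,cohort_b [expr_cohort()] objects with raw intensities on a
#'   shared probe-id namespace.
#' @param log2_transform apply the log2 transform (default `TRUE`). Set to
#'   `FALSE` for data already on a log scale; centering is always applied.
#' @return A list with elements `a` and `b`, the two normalized cohorts
#'   restricted to the common probes.
#' @export
intersect_and_normalize <- function(cohort_a, cohort_b, log2_transform = TRUE) {
  stopifnot(inherits(cohort_a, "expr_cohort"), inherits(cohort_b, "expr_cohort"))
  common <- intersect(probe_ids(cohort_a), probe_ids(cohort_b))
  if (!length(common)) stop("no probes are common to the two cohorts")
  norm1 <- function(x) {
    v <- x$values[common, , drop = FALSE]
    if (log2_transform) {
      if (any(v <= 0)) {
        bad <- which(v <= 0, arr.ind = TRUE)[1, ]
        stop(sprintf("non-positive intensity at probe '%s', sample '%s': %s",
                     rownames(v)[bad[1]], colnames(v)[bad[2]],
                     "log2 transform undefined"))
      }
      v <- log2(v)
    }
    v <- v - rowMeans(v)
    expr_cohort(v, labels = x$labels)
  }
  list(a = norm1(cohort_a), b = norm1(cohort_b))
}

#' Per-probe histogram entropy
#'
#' Shannon entropy (nats) of the histogram of one probe's values over
#' `ceiling(sqrt(n_samples))` equal-width bins spanning the probe's observed
#' range. A constant probe has entropy 0.
#'
#' @param x numeric vector of one probe's values across samples.
#' @return Entropy in nats.
#' @export
probe_entropy <- function(x) {
  n <- length(x)
  if (n < 2) stop("entropy undefined for fewer than 2 samples")
  nb <- ceiling(sqrt(n))
  r <- range(x)
  if (r[1] == r[2]) return(0)
  brk <- seq(r[1], r[2], length.out = nb + 1)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = nb)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

#' Remove low-variability probes by entropy percentile
#'
#' Computes each probe's histogram entropy and drops probes whose entropy is
#' strictly below the given percentile of the entropy distribution (ties at
#' the cutoff are kept). Probe order of survivors is preserved, and the
#' cutoff actually used is recorded in the `entropy_cutoff` attribute so a
#' second pass with `cutoff =` that value removes nothing.
#'
#' @param cohort a normalized [expr_cohort()].
#' @param percentile percentile of the entropy distribution to cut at,
#'   in (0, 100); default 10.
#' @param cutoff optional absolute entropy cutoff (nats) overriding the
#'   percentile computation, e.g. a recorded cutoff from a previous pass.
#' @return The filtered [expr_cohort()], with attributes `entropy_cutoff`
#'   and `entropy` (named vector of survivor entropies).
#' @export
entropy_filter <- function(cohort, percentile = 10, cutoff = NULL) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (ncol(cohort$values) < 2) stop("entropy undefined for fewer than 2 samples")
  ent <- apply(cohort$values, 1, probe_entropy)
  if (is.null(cutoff)) {
    if (!(percentile > 0 && percentile < 100))
      stop("`percentile` must lie in (0, 100)")
    cutoff <- stats::quantile(ent, percentile / 100, names = FALSE, type = 7)
  }
  keep <- ent >= cutoff   # strict "less than" removal: ties at cutoff kept
  out <- subset_cohort(cohort, probes = keep)
  attr(out, "entropy_cutoff") <- cutoff
  attr(out, "entropy") <- ent[keep]
  out
}

#' Pre-filter probes by case-versus-rest differential expression
#'
#' Retains probes whose Welch two-sample t-test, case subtype versus all
#' other samples, survives Benjamini-Hochberg FDR control at `alpha`. Used
#' as the paper-style preprocessing step that discards transcripts neither
#' variable nor disease-differential; for planted-edge recovery studies it
#' is usually left out (see the methods vignette).
#'
#' @param cohort a labeled, normalized [expr_cohort()].
#' @param case_label subtype defining the case group (e.g. `"M3"`).
#' @param alpha BH-FDR level; default 0.05.
#' @return The filtered [expr_cohort()] (probe order preserved).
#' @export
prefilter_transcripts <- function(cohort, case_label = "M3", alpha = 0.05) {
  de <- differential_expression(cohort, case_label = case_label, alpha = alpha)
  subset_cohort(cohort, probes = de$q < alpha)
}
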