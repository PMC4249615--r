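#' End-to-end consensus subnetwork pipeline
#'
#' Runs the full chain on two raw cohorts: probe intersection and
#' normalization, entropy filtering, per-cohort null calibration and
#' seed-anchored network inference, optional DPI pruning, consensus
#' intersection, per-cohort M3-versus-rest differential expression, and
#' extraction of the disease-specific subnetwork.
#'
#' The paper-style differential prefilter ([prefilter_transcripts()]) is off
#' by default: it restricts the probe universe to disease-differential
#' transcripts, which is appropriate when the goal is the disease subnetwork
#' alone but makes recovery of the full seed-anchored network impossible;
#' enable it with `prefilter_alpha`.
#'
#' @param cohort_a,cohort_b raw [expr_cohort()] objects with labels.
#' @param annotation probe -> gene map.
#' @param seed_genes character vector of seed gene symbols.
#' @param case_label disease subtype; default `"M3"`.
#' @param p_threshold_a,p_threshold_b per-cohort edge significance
#'   thresholds; defaults 1e-5 (desk-scale analogue of the asymmetric
#'   full-cohort thresholds).
#' @param entropy_percentile entropy-filter percentile; default 10.
#'   `NULL` skips the filter.
#' @param prefilter_alpha BH level of the differential prefilter, or `NULL`
#'   (default) to skip it.
#' @param dpi_tolerance DPI tolerance, or `NULL` to skip pruning; default
#'   0.1.
#' @param mode network mode, see [infer_relevance_network()].
#' @param alpha FDR level for subnetwork node inclusion; default 0.05.
#' @param min_component_genes component-size rule; default 10.
#' @param calib_pairs permutation pairs per cohort; default 1000.
#' @param rng_seed seed for the two null calibrations.
#' @param log2_transform passed to [intersect_and_normalize()].
#' @return List with `cohorts` (normalized, filtered), `calibrations`,
#'   `networks` (per cohort, after DPI), `consensus`, `de` (per cohort),
#'   `subnetwork`, `hubs`, `modules`.
#' @export
run_consensus_pipeline <- function(cohort_a, cohort_b, annotation, seed_genes,
                                   case_label = "M3",
                                   p_threshold_a = 1e-5, p_threshold_b = 1e-5,
                                   entropy_percentile = 10,
                                   prefilter_alpha = NULL,
                                   dpi_tolerance = 0.1,
                                   mode = "seed_restricted",
                                   alpha = 0.05, min_component_genes = 10,
                                   calib_pairs = 1000, rng_seed = 1,
                                   log2_transform = TRUE) {
  norm <- intersect_and_normalize(cohort_a, cohort_b,
                                  log2_transform = log2_transform)
  prep1 <- function(x) {
    if (!is.null(entropy_percentile))
      x <- entropy_filter(x, percentile = entropy_percentile)
    if (!is.null(prefilter_alpha))
      x <- prefilter_transcripts(x, case_label = case_label,
                                 alpha = prefilter_alpha)
    x
  }
  a <- prep1(norm$a)
  b <- prep1(norm$b)
  # keep the harmonized probe space identical after filtering
  common <- intersect(probe_ids(a), probe_ids(b))
  a <- subset_cohort(a, probes = common)
  b <- subset_cohort(b, probes = common)
  calib_a <- calibrate_null(a, n_pairs = calib_pairs, rng_seed = rng_seed)
  calib_b <- calibrate_null(b, n_pairs = calib_pairs, rng_seed = rng_seed + 1)
  seeds_a <- resolve_seeds(seed_genes, annotation, a)
  seeds_b <- resolve_seeds(seed_genes, annotation, b)
  net_a <- infer_relevance_network(a, seeds_a, p_threshold_a, calib_a,
                                   mode = mode)
  net_b <- infer_relevance_network(b, seeds_b, p_threshold_b, calib_b,
                                   mode = mode)
  if (!is.null(dpi_tolerance)) {
    net_a <- apply_dpi(net_a, tolerance = dpi_tolerance)
    net_b <- apply_dpi(net_b, tolerance = dpi_tolerance)
  }
  cons <- consensus_edges(net_a, net_b)
  de_a <- differential_expression(a, case_label = case_label, alpha = alpha)
  de_b <- differential_expression(b, case_label = case_label, alpha = alpha)
  subnet <- extract_apl_subnetwork(cons, de_a, de_b, annotation,
                                   alpha = alpha,
                                   min_component_genes = min_component_genes)
  hubs <- if (nrow(cons$edges))
    hub_table(cons, de_a, de_b, annotation = annotation) else NULL
  list(cohorts = list(a = a, b = b),
       calibrations = list(a = calib_a, b = calib_b),
       networks = list(a = net_a, b = net_b),
       consensus = cons,
       de = list(a = de_a, b = de_b),
       subnetwork = subnet,
       hubs = hubs,
       modules = detect_modules(cons, annotation = annotation))
}
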