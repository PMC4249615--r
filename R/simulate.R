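#' Configuration for the two-cohort synthetic generator
#'
#' Defines the planted structure the generator emulates: seed-anchored star
#' modules (each seed anchor drives a set of member genes with regulatory
#' strength `beta`), a small APL up-regulated module and a larger
#' down-regulated module wired to designated seed anchors and mean-shifted
#' in M3 samples only, independent background genes, 1-3 probes per gene,
#' two cohorts sharing a probe subset, and regulator miRNAs negatively
#' loaded on the down-module.
#'
#' Defaults are desk-scale: ~2,000 probes, ~150 and ~130 samples in the two
#' cohorts, 100 seed anchors; see the methods vignette for the rationale
#' behind every value.
#'
#' @param n_seed_anchors number of seed (anchor) genes; the seed list.
#' @param members_per_anchor member genes driven by each ordinary anchor.
#' @param n_background_genes independent background genes.
#' @param n_uninformative_genes genes with near-flat expression plus sparse
#'   hybridization-artifact outliers — the low-variability population the
#'   entropy filter exists to remove (histogram entropy is scale-free, so
#'   without such a population the filter would cut arbitrary signal
#'   probes).
#' @param uninformative_sd expression sd of uninformative genes.
#' @param artifact_rate per-sample probability of an artifact spike on an
#'   uninformative probe.
#' @param artifact_range log2-magnitude range of artifact spikes.
#' @param probes_per_gene integer range (min, max) of probes per gene.
#' @param samples_a,samples_b named counts of samples per FAB subtype for
#'   the two cohorts.
#' @param beta regulatory strength: member = beta * anchor + noise.
#' @param sigma_gene sd of gene-level member noise.
#' @param sigma_probe sd of probe-level measurement noise.
#' @param apl_up_size,apl_down_size module sizes in genes (each includes its
#'   designated anchor(s)).
#' @param n_down_anchors designated anchors of the down module.
#' @param apl_shift mean shift Delta added to module genes in M3 samples
#'   (+Delta up module, -Delta down module), log2 units.
#' @param anchor_latent_cor correlation among the down-module anchors
#'   (shared latent factor) tying the down stars into one community.
#' @param n_regulator_mirnas,n_decoy_mirnas miRNA counts.
#' @param mirna_loading negative loading of regulator miRNAs on the
#'   down-module activity.
#' @param mirna_shift extra M3 up-shift added to regulator miRNAs.
#' @param shared_probe_fraction fraction of probes measured on both
#'   platforms (each gene keeps at least one shared probe).
#' @param seed integer RNG seed; same config + seed gives bit-identical
#'   output.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_seed_anchors = 100,
                             members_per_anchor = 6,
                             n_background_genes = 200,
                             n_uninformative_genes = 300,
                             uninformative_sd = 0.15,
                             artifact_rate = 0.02,
                             artifact_range = c(3, 6),
                             probes_per_gene = c(1, 3),
                             samples_a = c(M0 = 15, M1 = 30, M2 = 30,
                                           M3 = 20, M4 = 30, M5 = 25),
                             samples_b = c(M0 = 12, M1 = 25, M2 = 28,
                                           M3 = 19, M4 = 26, M5 = 20),
                             beta = 1,
                             sigma_gene = 0.5,
                             sigma_probe = 0.3,
                             apl_up_size = 30,
                             apl_down_size = 100,
                             n_down_anchors = 3,
                             apl_shift = 1.5,
                             anchor_latent_cor = 0.6,
                             n_regulator_mirnas = 1,
                             n_decoy_mirnas = 30,
                             mirna_loading = -0.8,
                             mirna_shift = 0.5,
                             shared_probe_fraction = 0.8,
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_seed_anchors, cfg$members_per_anchor,
              cfg$n_background_genes, cfg$apl_up_size, cfg$apl_down_size,
              cfg$n_down_anchors, unlist(cfg$samples_a), unlist(cfg$samples_b))
  if (any(counts <= 0)) stop("all counts must be positive")
  if (!(cfg$shared_probe_fraction > 0 && cfg$shared_probe_fraction <= 1))
    stop("shared_probe_fraction must lie in (0, 1]")
  if (cfg$apl_shift < 0) stop("apl_shift must be >= 0")
  if (cfg$n_down_anchors + 1 > cfg$n_seed_anchors)
    stop("not enough anchors for the designated module anchors")
  if (cfg$apl_up_size < 2 || cfg$apl_down_size <= cfg$n_down_anchors)
    stop("module sizes must exceed their designated anchor counts")
  if (length(cfg$probes_per_gene) != 2 || any(cfg$probes_per_gene < 1) ||
      cfg$probes_per_gene[1] > cfg$probes_per_gene[2])
    stop("probes_per_gene must be an increasing pair of positive integers")
  if (!all(c("M3") %in% names(cfg$samples_a)) ||
      !all(c("M3") %in% names(cfg$samples_b)))
    stop("both cohorts need M3 samples")
  if (cfg$mirna_loading >= 0) stop("mirna_loading must be negative")
  structure(cfg, class = "generator_config")
}

# Gene catalogue implied by a config: roles, anchor wiring, modules.
gene_catalogue <- function(cfg) {
  na <- cfg$n_seed_anchors
  anchors <- sprintf("GA%03d", seq_len(na))
  up_anchor <- anchors[1]
  down_anchors <- anchors[1 + seq_len(cfg$n_down_anchors)]
  regular_anchors <- setdiff(anchors, c(up_anchor, down_anchors))
  up_members <- sprintf("GU%03d", seq_len(cfg$apl_up_size - 1))
  down_members <- sprintf("GD%03d",
                          seq_len(cfg$apl_down_size - cfg$n_down_anchors))
  reg_members <- sprintf("GM%04d",
                         seq_len(length(regular_anchors) *
                                   cfg$members_per_anchor))
  background <- sprintf("GB%03d", seq_len(cfg$n_background_genes))
  uninformative <- sprintf("GN%03d", seq_len(cfg$n_uninformative_genes))
  gene <- c(anchors, up_members, down_members, reg_members, background,
            uninformative)
  role <- c(rep("anchor", na),
            rep("member", length(up_members) + length(down_members) +
                  length(reg_members)),
            rep("background", length(background)),
            rep("uninformative", length(uninformative)))
  anchor_of <- c(rep(NA_character_, na),
                 rep(up_anchor, length(up_members)),
                 down_anchors[(seq_along(down_members) - 1) %%
                                cfg$n_down_anchors + 1],
                 rep(regular_anchors, each = cfg$members_per_anchor),
                 rep(NA_character_, length(background) +
                       length(uninformative)))
  module <- rep("none", length(gene))
  module[gene %in% c(up_anchor, up_members)] <- "apl_up"
  module[gene %in% c(down_anchors, down_members)] <- "apl_down"
  module[gene %in% c(background, uninformative)] <- "background"
  data.frame(gene = gene, role = role, anchor = anchor_of, module = module,
             stringsAsFactors = FALSE)
}

#' Generate two synthetic AML cohorts with planted structure
#'
#' Gene-level model: each anchor is standard normal (the down-module anchors
#' share a latent factor giving them pairwise correlation
#' `anchor_latent_cor`); each member gene is `beta * anchor + N(0,
#' sigma_gene)`; background genes are independent standard normal. Module
#' genes additionally receive the `+/- apl_shift` mean shift in M3 samples.
#' Probe intensities are `2^(gene value + probe noise + 8)` — strictly
#' positive raw values ready for [intersect_and_normalize()]. Cohort B is an
#' independent draw from the same truth with its own sample counts, and the
#' two cohorts share `shared_probe_fraction` of the probe universe (every
#' gene keeps at least one shared probe).
#'
#' @param cfg a [generator_config()].
#' @return List with `cohort_a`, `cohort_b` ([expr_cohort()] raw
#'   intensities), `annotation` (probe -> gene), `seed_genes` (the anchor
#'   gene symbols), and `truth` (class `truth_model`: `edges`, `indirect`,
#'   `modules`, `shifts`, `regulators`, `annotation`, `seed`).
#' @export
generate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed %% .Machine$integer.max)
  cat_df <- gene_catalogue(cfg)
  ng <- nrow(cat_df)

  # Probe universe (shared across cohorts, like array designs). Multiplicity
  # and platform assignment are deterministic in the config so that changing
  # only the seed never changes dimensions or truth-structure sizes.
  k <- rep(seq(cfg$probes_per_gene[1], cfg$probes_per_gene[2]),
           length.out = ng)
  probe_gene <- rep(cat_df$gene, k)
  probe_id <- unlist(lapply(seq_len(ng), function(i)
    sprintf("%s_p%d", cat_df$gene[i], seq_len(k[i]))))
  annotation <- stats::setNames(probe_gene, probe_id)
  first_of_gene <- !duplicated(probe_gene)
  n_extra <- sum(!first_of_gene)
  q_extra <- if (n_extra > 0)
    min(1, max(0, (cfg$shared_probe_fraction * length(probe_id) - ng) /
                 n_extra)) else 1
  shared <- first_of_gene
  if (n_extra > 0) {   # evenly striped deterministic selection of extras
    i_extra <- seq_len(n_extra)
    shared[!first_of_gene] <-
      floor(i_extra * q_extra) > floor((i_extra - 1) * q_extra)
  }
  excl <- which(!shared)
  in_a <- shared
  in_b <- shared
  if (length(excl)) {
    to_a <- excl[seq_along(excl) %% 2 == 1]
    in_a[to_a] <- TRUE
    in_b[setdiff(excl, to_a)] <- TRUE
  }

  draw_cohort <- function(counts, prefix) {
    n <- sum(counts)
    labels <- rep(names(counts), counts)
    sid <- sprintf("%s_%s_%02d", prefix, labels,
                   unlist(lapply(counts, seq_len)))
    is_m3 <- labels == "M3"
    g <- matrix(0, ng, n, dimnames = list(cat_df$gene, sid))
    lat <- sqrt(cfg$anchor_latent_cor)
    idio <- sqrt(1 - cfg$anchor_latent_cor)
    f <- stats::rnorm(n)
    is_anchor <- cat_df$role == "anchor"
    is_down_anchor <- is_anchor & cat_df$module == "apl_down"
    g[is_anchor, ] <- matrix(stats::rnorm(sum(is_anchor) * n),
                             sum(is_anchor), n)
    g[is_down_anchor, ] <- lat * rep(f, each = sum(is_down_anchor)) +
      idio * matrix(stats::rnorm(sum(is_down_anchor) * n),
                    sum(is_down_anchor), n)
    is_member <- cat_df$role == "member"
    g[is_member, ] <- cfg$beta * g[cat_df$anchor[is_member], , drop = FALSE] +
      matrix(stats::rnorm(sum(is_member) * n, sd = cfg$sigma_gene),
             sum(is_member), n)
    is_bg <- cat_df$role == "background"
    g[is_bg, ] <- matrix(stats::rnorm(sum(is_bg) * n), sum(is_bg), n)
    is_uninf <- cat_df$role == "uninformative"
    g[is_uninf, ] <- matrix(stats::rnorm(sum(is_uninf) * n,
                                         sd = cfg$uninformative_sd),
                            sum(is_uninf), n)
    shift <- ifelse(cat_df$module == "apl_up", cfg$apl_shift,
                    ifelse(cat_df$module == "apl_down", -cfg$apl_shift, 0))
    g[, is_m3] <- g[, is_m3, drop = FALSE] + shift
    pv <- g[probe_gene, , drop = FALSE] +
      matrix(stats::rnorm(length(probe_id) * n, sd = cfg$sigma_probe),
             length(probe_id), n)
    # sparse hybridization-artifact spikes on uninformative probes: they
    # stretch the per-probe range so these probes fill the low-entropy tail
    uninf_rows <- which(probe_gene %in% cat_df$gene[is_uninf])
    if (length(uninf_rows)) {
      spike <- matrix(stats::rbinom(length(uninf_rows) * n, 1,
                                    cfg$artifact_rate) *
                        stats::runif(length(uninf_rows) * n,
                                     cfg$artifact_range[1],
                                     cfg$artifact_range[2]),
                      length(uninf_rows), n)
      pv[uninf_rows, ] <- pv[uninf_rows, , drop = FALSE] + spike
    }
    rownames(pv) <- probe_id
    expr_cohort(2^(pv + 8), labels = stats::setNames(labels, sid))
  }

  cohort_a <- draw_cohort(cfg$samples_a, "A")
  cohort_b <- draw_cohort(cfg$samples_b, "B")
  cohort_a <- subset_cohort(cohort_a, probes = in_a)
  cohort_b <- subset_cohort(cohort_b, probes = in_b)

  members <- cat_df[cat_df$role == "member", ]
  edges <- data.frame(gene_a = pmin(members$anchor, members$gene),
                      gene_b = pmax(members$anchor, members$gene),
                      stringsAsFactors = FALSE)
  indirect <- do.call(rbind, lapply(split(members$gene, members$anchor),
    function(ms) {
      if (length(ms) < 2) return(NULL)
      cmb <- utils::combn(sort(ms), 2)
      data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
  rownames(indirect) <- NULL
  modules <- list(
    apl_up = cat_df$gene[cat_df$module == "apl_up"],
    apl_down = cat_df$gene[cat_df$module == "apl_down"],
    background = cat_df$gene[cat_df$module == "background"])
  shifts <- stats::setNames(
    ifelse(cat_df$module == "apl_up", cfg$apl_shift,
           ifelse(cat_df$module == "apl_down", -cfg$apl_shift, 0)),
    cat_df$gene)
  regulators <- if (cfg$n_regulator_mirnas > 0)
    stats::setNames(rep(list(modules$apl_down), cfg$n_regulator_mirnas),
                    sprintf("miR-R%02d", seq_len(cfg$n_regulator_mirnas)))
  else list()
  truth <- structure(list(edges = edges, indirect = indirect,
                          modules = modules, shifts = shifts,
                          regulators = regulators, annotation = annotation,
                          catalogue = cat_df, seed = cfg$seed),
                     class = "truth_model")
  list(cohort_a = cohort_a, cohort_b = cohort_b, annotation = annotation,
       seed_genes = cat_df$gene[cat_df$role == "anchor"], truth = truth)
}

#' Generate miRNA expression tied to the planted down-module
#'
#' Regulator miRNAs track the (standardized, sign-flipped) mean activity of
#' their target genes in the given cohort with the configured negative
#' loading, plus an extra M3 up-shift and independent noise scaled so the
#' miRNA has roughly unit variance; because the targets are down-shifted in
#' M3, the regulators are up-regulated there both through the loading and
#' the explicit shift. Decoy miRNAs are independent standard normal.
#'
#' @param cfg the [generator_config()] used to build the cohort.
#' @param truth the `truth_model` from [generate_cohorts()].
#' @param cohort one of the generated cohorts (raw intensities or
#'   normalized; raw values are log2-transformed and centered internally).
#' @return An [expr_cohort()] of miRNA expression (log2-like scale) over the
#'   cohort's samples.
#' @export
generate_mirnas <- function(cfg, truth, cohort) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(truth, "truth_model"),
            inherits(cohort, "expr_cohort"))
  set.seed((cfg$seed + 1L) %% .Machine$integer.max)
  v <- cohort$values
  if (all(v > 0) && max(v) > 50) {       # raw intensities
    v <- log2(v)
    v <- v - rowMeans(v)
  }
  n <- ncol(v)
  is_m3 <- cohort$labels == "M3"
  lam <- cfg$mirna_loading
  noise_sd <- sqrt(max(0.05, 1 - lam^2))
  rows <- list()
  for (id in names(truth$regulators)) {
    probes <- names(truth$annotation)[truth$annotation %in%
                                        truth$regulators[[id]]]
    probes <- intersect(probes, rownames(v))
    act <- colMeans(v[probes, , drop = FALSE])
    act <- (act - mean(act)) / stats::sd(act)
    rows[[id]] <- lam * act + cfg$mirna_shift * is_m3 +
      stats::rnorm(n, sd = noise_sd)
  }
  for (i in seq_len(cfg$n_decoy_mirnas))
    rows[[sprintf("miR-D%02d", i)]] <- stats::rnorm(n)
  m <- do.call(rbind, rows)
  colnames(m) <- colnames(v)
  expr_cohort(m, labels = cohort$labels)
}

#' Generate a treatment time-course relaxing planted shifts to baseline
#'
#' Each APL-module gene's expected expression relaxes from its M3-shifted
#' level toward baseline as `shift * exp(-t / tau)`; the table reports log2
#' fold change versus the first timepoint, so a module gene's expected
#' trajectory is `shift * (exp(-t/tau) - 1)` plus `N(0, noise_sd)` noise
#' (the reference column is exactly 0). Background genes fluctuate around 0.
#'
#' @param cfg the [generator_config()].
#' @param truth the `truth_model`.
#' @param timepoints hours, starting at 0, strictly increasing.
#' @param tau relaxation time constant (hours), > 0.
#' @param noise_sd measurement noise sd on log2 fold changes; default 0.05.
#' @param n_background background genes to include; default 50.
#' @return A [time_course()] over module (+ background) genes.
#' @export
generate_timecourse <- function(cfg, truth, timepoints = c(0, 6, 12, 24, 48, 72),
                                tau = 12, noise_sd = 0.05, n_background = 50) {
  stopifnot(inherits(cfg, "generator_config"), inherits(truth, "truth_model"))
  if (tau <= 0) stop("tau must be > 0")
  if (timepoints[1] != 0) stop("timepoints must start at 0")
  set.seed((cfg$seed + 2L) %% .Machine$integer.max)
  genes <- c(truth$modules$apl_up, truth$modules$apl_down,
             utils::head(truth$modules$background, n_background))
  shift <- truth$shifts[genes]
  m <- sapply(timepoints, function(t) {
    if (t == 0) return(rep(0, length(genes)))
    shift * (exp(-t / tau) - 1) + stats::rnorm(length(genes), sd = noise_sd)
  })
  rownames(m) <- genes
  time_course(m, timepoints)
}

#' Evaluate recovery of the planted structure
#'
#' Compares an inferred network (or extracted subnetwork) against the truth
#' model at gene level: inferred probe-pair edges are mapped to gene pairs
#' (same-gene pairs dropped), precision and recall are computed against the
#' planted anchor-member edges, and the gene sets are compared to the
#' planted APL modules by Jaccard index. Indirect member-member pairs (two
#' members sharing an anchor) are counted as false positives when DPI
#' pruning was applied — they are exactly what pruning should remove — and
#' reported separately otherwise. Optionally scores a miRNA ranking by the
#' fraction of planted regulators in its top k.
#'
#' @param inferred an `mi_network` or `apl_subnetwork`.
#' @param truth the `truth_model` from [generate_cohorts()].
#' @param dpi_applied whether indirect pairs count as false positives
#'   (default `TRUE`).
#' @param mirna_ranking optional [anticorrelation_ranking()] result.
#' @param top_k ranking depth for the miRNA hit rate; defaults to the number
#'   of planted regulators.
#' @return List: `precision`, `recall`, `n_true_edges`, `n_inferred_edges`,
#'   `n_indirect_recovered`, `jaccard_up`, `jaccard_down`, `jaccard_modules`,
#'   `mirna_hit_rate` (`NA` without a ranking).
#' @export
evaluate_recovery <- function(inferred, truth, dpi_applied = TRUE,
                              mirna_ranking = NULL, top_k = NULL) {
  stopifnot(inherits(truth, "truth_model"))
  if (!nrow(truth$edges)) stop("truth model has no planted edges")
  edges <- if (inherits(inferred, "mi_network")) inferred$edges
           else inferred$edges
  ann <- truth$annotation
  ga <- unname(ann[edges$from])
  gb <- unname(ann[edges$to])
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  key <- unique(paste(pmin(ga[keep], gb[keep]),
                      pmax(ga[keep], gb[keep]), sep = "\r"))
  true_key <- paste(truth$edges$gene_a, truth$edges$gene_b, sep = "\r")
  ind_key <- paste(truth$indirect$gene_a, truth$indirect$gene_b, sep = "\r")
  tp <- sum(key %in% true_key)
  n_ind <- sum(key %in% ind_key)
  denom <- if (dpi_applied) length(key) else length(key) - n_ind
  precision <- if (denom > 0) tp / denom else NA_real_
  recall <- tp / length(true_key)
  genes <- if (inherits(inferred, "apl_subnetwork"))
    subnetwork_genes(inferred)
  else unique(unname(ann[inferred$nodes]))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  hit <- NA_real_
  if (!is.null(mirna_ranking) && length(truth$regulators)) {
    if (is.null(top_k)) top_k <- length(truth$regulators)
    top <- utils::head(mirna_ranking$mirna, top_k)
    hit <- mean(names(truth$regulators) %in% top)
  }
  list(precision = precision, recall = recall,
       n_true_edges = length(true_key), n_inferred_edges = length(key),
       n_indirect_recovered = n_ind,
       jaccard_up = jac(genes, truth$modules$apl_up),
       jaccard_down = jac(genes, truth$modules$apl_down),
       jaccard_modules = jac(genes, c(truth$modules$apl_up,
                                      truth$modules$apl_down)),
       mirna_hit_rate = hit)
}
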