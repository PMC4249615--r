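#' Write a network as SIF plus attribute tables
#'
#' Produces `<prefix>.sif` (node1 TAB "mi" TAB node2), an edge-attribute TSV
#' (`node1`, `node2`, `mi_nats`, `p_value` — or the per-cohort quadruple for
#' consensus networks) and a node-attribute TSV (`node`, `is_seed`,
#' `degree`).
#'
#' @param net an `mi_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; default `"network"`.
#' @return Invisibly, the paths written.
#' @export
write_mi_network <- function(net, dir, prefix = "network") {
  stopifnot(inherits(net, "mi_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  e <- net$edges
  writeLines(if (nrow(e)) paste(e$from, "mi", e$to, sep = "\t") else character(),
             sif)
  eattr <- file.path(dir, paste0(prefix, "_edges.tsv"))
  ed <- if ("mi" %in% names(e))
    data.frame(node1 = e$from, node2 = e$to, mi_nats = e$mi, p_value = e$p)
  else
    data.frame(node1 = e$from, node2 = e$to, mi_a_nats = e$mi_a,
               mi_b_nats = e$mi_b, p_a = e$p_a, p_b = e$p_b)
  utils::write.table(ed, eattr, sep = "\t", quote = FALSE, row.names = FALSE)
  nattr <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  deg <- if (length(net$nodes)) igraph::degree(as_igraph(net))[net$nodes]
         else integer()
  utils::write.table(
    data.frame(node = net$nodes, is_seed = unname(net$is_seed),
               degree = as.integer(deg)),
    nattr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, eattr, nattr))
}

#' Write a null calibration as TSV with a metadata header
#'
#' Permutation MI samples, one per line, preceded by `#`-prefixed metadata
#' (fit coefficients, seed, pair count).
#'
#' @param calib an [calibrate_null()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "mi_null_calibration"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# a\t%.10g", calib$a),
               sprintf("# b\t%.10g", calib$b),
               sprintf("# rng_seed\t%d", calib$rng_seed),
               sprintf("# n_pairs\t%d", calib$n_pairs),
               sprintf("# n_samples\t%d", calib$n_samples),
               "mi_nats"), con)
  writeLines(sprintf("%.10g", calib$samples), con)
  invisible(path)
}

#' Write differential-expression results as TSV
#' @param de a [differential_expression()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_diff_tsv <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an extracted subnetwork as SIF plus node attributes
#'
#' `<prefix>.sif` plus `<prefix>_nodes.tsv` with columns `node`, `gene`,
#' `direction`, `component`, `is_seed` — loadable by standard graph viewers.
#'
#' @param subnet an [extract_apl_subnetwork()] result.
#' @param dir output directory.
#' @param prefix file-name prefix; default `"subnetwork"`.
#' @return Invisibly, the paths written.
#' @export
write_subnetwork <- function(subnet, dir, prefix = "subnetwork") {
  stopifnot(inherits(subnet, "apl_subnetwork"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  e <- subnet$edges
  writeLines(if (nrow(e)) paste(e$from, "mi", e$to, sep = "\t") else character(),
             sif)
  nattr <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(
    subnet$nodes[, c("node", "gene", "direction", "component", "is_seed")],
    nattr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, nattr))
}

#' Write a subtype-coloring matrix as TSV
#' @param coloring matrix from [subtype_coloring()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_coloring_tsv <- function(coloring, path) {
  df <- data.frame(node = rownames(coloring), coloring,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression cohort as TSV (plus optional label TSV)
#' @param cohort an [expr_cohort()].
#' @param path output TSV path.
#' @param labels_path optional path for a two-column sample/subtype TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(cohort, path, labels_path = NULL) {
  stopifnot(inherits(cohort, "expr_cohort"))
  df <- data.frame(probe_id = probe_ids(cohort), cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && !is.null(cohort$labels))
    utils::write.table(
      data.frame(sample = names(cohort$labels),
                 subtype = unname(cohort$labels)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  invisible(path)
}
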