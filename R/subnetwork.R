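#' Extract the disease-specific subnetwork from a consensus network
#'
#' Keeps the consensus-network nodes that are significantly differential
#' (`q < alpha`) in BOTH cohorts with concordant direction, induces the
#' subgraph on them, and drops connected components containing no more than
#' `min_component_genes` distinct genes (isolated transcripts and small
#' circuits). Components are labeled deterministically, largest first.
#'
#' @param consensus an `mi_network` from [consensus_edges()].
#' @param de_a,de_b [differential_expression()] results for the two cohorts.
#' @param annotation named character vector, probe -> gene symbol, used for
#'   the gene-level component-size rule.
#' @param alpha FDR level for node inclusion; default 0.05.
#' @param min_component_genes components with at most this many distinct
#'   genes are discarded; default 10.
#' @param concordant require the same direction in both cohorts (default
#'   `TRUE`; with `FALSE` only dual significance is required and the
#'   direction of cohort A is reported).
#' @return An object of class `apl_subnetwork`: list with `edges` (consensus
#'   edges among retained nodes), `nodes` (data.frame: node, gene, direction,
#'   direction_a, direction_b, component, is_seed) and `components`
#'   (data.frame: component, n_probes, n_genes).
#' @export
extract_apl_subnetwork <- function(consensus, de_a, de_b, annotation,
                                   alpha = 0.05, min_component_genes = 10,
                                   concordant = TRUE) {
  stopifnot(inherits(consensus, "mi_network"))
  nodes <- consensus$nodes
  da <- de_a[match(nodes, de_a$probe), ]
  db <- de_b[match(nodes, de_b$probe), ]
  sig <- !is.na(da$q) & !is.na(db$q) & da$q < alpha & db$q < alpha
  if (concordant) {
    keep <- sig & da$direction == db$direction & da$direction != "ns"
  } else {
    keep <- sig & da$direction != "ns" & db$direction != "ns"
  }
  kept_nodes <- nodes[keep]
  e <- consensus$edges
  e <- e[e$from %in% kept_nodes & e$to %in% kept_nodes, , drop = FALSE]
  sub <- mi_network(e, seed_probes = names(consensus$is_seed)[consensus$is_seed])
  # nodes with no surviving edge form singleton components
  isolated <- setdiff(kept_nodes, sub$nodes)
  mod <- detect_modules(sub, annotation = annotation)
  ok_comp <- mod$sizes$component[mod$sizes$n_genes > min_component_genes]
  memb <- mod$membership[mod$membership %in% ok_comp]
  if (!length(memb))
    warning("empty subnetwork: no component exceeds the gene-size threshold")
  final_nodes <- as.character(names(memb))
  e <- e[e$from %in% final_nodes & e$to %in% final_nodes, , drop = FALSE]
  idx <- match(final_nodes, nodes)
  ntab <- data.frame(
    node = final_nodes,
    gene = unname(annotation[final_nodes]),
    direction = da$direction[idx],
    direction_a = da$direction[idx],
    direction_b = db$direction[idx],
    component = as.integer(unname(memb)),
    is_seed = unname(consensus$is_seed[final_nodes]),
    stringsAsFactors = FALSE)
  ntab <- ntab[order(ntab$component, ntab$node), , drop = FALSE]
  rownames(ntab) <- NULL
  comp <- mod$sizes[mod$sizes$component %in% ok_comp, , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(edges = e, nodes = ntab, components = comp,
                 alpha = alpha, min_component_genes = min_component_genes,
                 concordant = concordant,
                 n_candidates = length(kept_nodes),
                 n_isolated_dropped = length(isolated)),
            class = "apl_subnetwork")
}

#' @export
print.apl_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<apl_subnetwork> %d nodes (%d genes), %d edges, %d component(s)\n",
    nrow(x$nodes), length(unique(x$nodes$gene)), nrow(x$edges),
    nrow(x$components)))
  up <- sum(x$nodes$direction == "up")
  cat(sprintf("  directions: %d up / %d down; dropped %d candidate node(s)\n",
              up, nrow(x$nodes) - up,
              x$n_candidates - nrow(x$nodes)))
  invisible(x)
}

#' Genes of a subnetwork
#' @param subnet an [extract_apl_subnetwork()] result.
#' @return Character vector of distinct gene symbols.
#' @export
subnetwork_genes <- function(subnet) {
  stopifnot(inherits(subnet, "apl_subnetwork"))
  unique(subnet$nodes$gene)
}
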