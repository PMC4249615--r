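#' Mutual-information relevance network
#'
#' Internal constructor for the undirected MI network class. Edges are stored
#' once per unordered pair with endpoints in canonical (lexicographic) order;
#' self-edges are rejected.
#'
#' @param edges data.frame with columns `from`, `to` plus numeric attributes
#'   (at least `mi`, `p` for single-cohort networks).
#' @param seed_probes character vector of seed probe ids.
#' @param meta list of provenance metadata (mode, thresholds, dpi settings).
#' @return An object of class `mi_network`: list with `edges`, `nodes`,
#'   `is_seed` (named logical over nodes) and `meta`.
#' @keywords internal
mi_network <- function(edges, seed_probes = character(), meta = list()) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicated undirected edge")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(edges = edges, nodes = nodes,
                 is_seed = stats::setNames(nodes %in% seed_probes, nodes),
                 meta = meta),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("<mi_network> %d nodes, %d edges (%d seed nodes)\n",
              length(x$nodes), nrow(x$edges), sum(x$is_seed)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Infer a seed-anchored relevance network
#'
#' Estimates mutual information for probe pairs — in `seed_restricted` mode
#' (the default) every (seed probe, other probe) pair, in `all_pairs` mode
#' every pair — converts each MI to an edge p-value through the calibrated
#' null, and keeps edges with `p < p_threshold`. Nodes are the endpoints of
#' kept edges.
#'
#' @param cohort a normalized [expr_cohort()].
#' @param seeds a [resolve_seeds()] result (ignored for node selection in
#'   `all_pairs` mode but still recorded in the seed flags).
#' @param p_threshold edge significance threshold in (0, 1).
#' @param calib an [calibrate_null()] result for this cohort.
#' @param mode `"seed_restricted"` or `"all_pairs"`.
#' @param min_split,alpha_split estimator controls, see [estimate_mi()].
#' @return An `mi_network` whose edges carry `mi` (nats) and `p`.
#' @export
infer_relevance_network <- function(cohort, seeds, p_threshold, calib,
                                    mode = c("seed_restricted", "all_pairs"),
                                    min_split = 8, alpha_split = 0.05) {
  stopifnot(inherits(cohort, "expr_cohort"),
            inherits(calib, "mi_null_calibration"))
  mode <- match.arg(mode)
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("`p_threshold` must lie in (0, 1)")
  v <- cohort$values
  pid <- rownames(v)
  seed_probes <- intersect(seeds$probes, pid)
  if (!length(seed_probes)) stop("no seed probe present in the matrix")
  ranks <- rank_rows(v)
  if (mode == "seed_restricted") {
    si <- match(seed_probes, pid)
    ii <- rep(si, each = length(pid))
    jj <- rep(seq_along(pid), times = length(si))
    keep <- ii < jj | (jj < ii & !(pid[jj] %in% seed_probes))
    ii2 <- pmin(ii[keep], jj[keep])
    jj2 <- pmax(ii[keep], jj[keep])
    key <- ii2 * (length(pid) + 1) + jj2
    dup <- duplicated(key)
    i <- ii2[!dup]
    j <- jj2[!dup]
  } else {
    cmb <- utils::combn(length(pid), 2L)
    i <- cmb[1L, ]
    j <- cmb[2L, ]
  }
  mi <- mi_row_pairs(ranks, i, j, min_split = min_split,
                     alpha_split = alpha_split)
  p <- mi_pvalue(calib, mi)
  hit <- p < p_threshold
  edges <- data.frame(from = pid[i[hit]], to = pid[j[hit]],
                      mi = mi[hit], p = p[hit], stringsAsFactors = FALSE)
  if (!nrow(edges))
    warning("no edge passes the significance threshold; empty network")
  mi_network(edges, seed_probes = seed_probes,
             meta = list(mode = mode, p_threshold = p_threshold,
                         calibration_seed = calib$rng_seed,
                         min_split = min_split, alpha_split = alpha_split))
}

#' Prune indirect edges by the data-processing inequality
#'
#' For every triangle (i, j, k) in the network, edge (i, j) is marked for
#' removal when `mi(i,j) < (1 - tolerance) * min(mi(i,k), mi(j,k))`; in a
#' dependence chain X - Y - Z the X-Z dependence is bounded by the weaker of
#' the two direct ones, so the weakest edge of a triangle is the indirect
#' candidate. All marks are evaluated on the input graph and removals applied
#' simultaneously, so the result does not depend on edge order.
#'
#' @param net an `mi_network` with an `mi` edge attribute (for consensus
#'   networks the minimum of the two cohort MI values is used).
#' @param tolerance fraction in \[0, 1); 0 removes every strictly-weakest
#'   triangle edge, larger values spare edges close to the bound.
#' @return The pruned `mi_network` (a subgraph of the input).
#' @export
apply_dpi <- function(net, tolerance = 0.1) {
  stopifnot(inherits(net, "mi_network"))
  if (!(tolerance >= 0 && tolerance < 1)) stop("`tolerance` must be in [0,1)")
  if (!nrow(net$edges)) return(net)
  mi <- if ("mi" %in% names(net$edges)) net$edges$mi
        else pmin(net$edges$mi_a, net$edges$mi_b)
  g <- as_igraph(net)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  if (!ncol(tri)) {
    net$meta$dpi_tolerance <- tolerance
    return(net)
  }
  eid <- rbind(
    igraph::get_edge_ids(g, as.vector(rbind(tri[1, ], tri[2, ]))),
    igraph::get_edge_ids(g, as.vector(rbind(tri[2, ], tri[3, ]))),
    igraph::get_edge_ids(g, as.vector(rbind(tri[1, ], tri[3, ]))))
  drop <- logical(nrow(net$edges))
  for (t in seq_len(ncol(tri))) {
    e <- eid[, t]
    m <- mi[e]
    for (s in 1:3) {
      others <- m[-s]
      if (m[s] < (1 - tolerance) * min(others)) drop[e[s]] <- TRUE
    }
  }
  out <- mi_network(net$edges[!drop, , drop = FALSE],
                    seed_probes = names(net$is_seed)[net$is_seed],
                    meta = net$meta)
  out$meta$dpi_tolerance <- tolerance
  out
}

#' Intersect two cohort networks into a consensus network
#'
#' Keeps the unordered edges present in both inputs; per-edge MI and p-value
#' attributes from both cohorts are retained as `mi_a`, `mi_b`, `p_a`, `p_b`.
#' Nodes are the endpoints of surviving edges; a node is flagged as seed if
#' it is a seed in either input.
#'
#' @param net_a,net_b `mi_network` objects on a harmonized probe namespace.
#' @return An `mi_network` with the four per-cohort edge attributes.
#' @export
consensus_edges <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "mi_network"), inherits(net_b, "mi_network"))
  ea <- net_a$edges
  eb <- net_b$edges
  key_a <- paste(ea$from, ea$to, sep = "\r")
  key_b <- paste(eb$from, eb$to, sep = "\r")
  hit <- match(key_a, key_b)
  keep <- !is.na(hit)
  edges <- data.frame(from = ea$from[keep], to = ea$to[keep],
                      mi_a = ea$mi[keep], mi_b = eb$mi[hit[keep]],
                      p_a = ea$p[keep], p_b = eb$p[hit[keep]],
                      stringsAsFactors = FALSE)
  mi_network(edges,
             seed_probes = union(names(net_a$is_seed)[net_a$is_seed],
                                 names(net_b$is_seed)[net_b$is_seed]),
             meta = list(mode = "consensus",
                         meta_a = net_a$meta, meta_b = net_b$meta))
}

#' Connected components of a network as modules
#'
#' Labels connected components deterministically — component 1 is the
#' largest, ties broken by smallest member node id — and reports sizes in
#' probes and, when an annotation is given, in distinct genes.
#'
#' @param net an `mi_network`.
#' @param annotation optional named character vector, probe -> gene.
#' @return List with `membership` (named integer vector over nodes) and
#'   `sizes` (data.frame: component, n_probes, n_genes).
#' @export
detect_modules <- function(net, annotation = NULL) {
  stopifnot(inherits(net, "mi_network"))
  if (!length(net$nodes))
    return(list(membership = integer(0),
                sizes = data.frame(component = integer(0),
                                   n_probes = integer(0),
                                   n_genes = integer(0))))
  comp <- igraph::components(as_igraph(net))
  memb <- comp$membership
  first_node <- tapply(names(memb), memb, min)
  ord <- order(-comp$csize, first_node)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  memb <- stats::setNames(relabel[memb], names(memb))
  n_genes <- if (is.null(annotation)) {
    tapply(names(memb), memb, length)
  } else {
    tapply(names(memb), memb, function(p) length(unique(annotation[p])))
  }
  sizes <- data.frame(component = sort(unique(memb)))
  sizes$n_probes <- as.integer(table(memb)[as.character(sizes$component)])
  sizes$n_genes <- as.integer(n_genes[as.character(sizes$component)])
  list(membership = memb[order(names(memb))], sizes = sizes)
}
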