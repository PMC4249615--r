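#' Subnetwork state across FAB subtypes
#'
#' For each subtype label, runs a one-vs-rest differential test restricted to
#' the subnetwork's nodes (BH-FDR within that node set) and records each
#' node's state: `up`, `down`, or `ns` — the per-subtype filled/empty node
#' coloring of the subnetwork. Subtypes with fewer than 2 samples yield an
#' all-`ns` column with a warning.
#'
#' @param subnet an [extract_apl_subnetwork()] result (or any object with a
#'   `nodes$node` column; a character vector of probes also works).
#' @param cohort a labeled [expr_cohort()] containing the subnetwork probes.
#' @param alpha FDR level per subtype column; default 0.05.
#' @param subtypes subtype labels to profile; default all labels present.
#' @return A character matrix, nodes x subtypes, values in
#'   `c("up", "down", "ns")`.
#' @export
subtype_coloring <- function(subnet, cohort, alpha = 0.05, subtypes = NULL) {
  stopifnot(inherits(cohort, "expr_cohort"))
  nodes <- if (is.character(subnet)) subnet else subnet$nodes$node
  nodes <- intersect(nodes, probe_ids(cohort))
  if (!length(nodes)) stop("no subnetwork node present in the cohort")
  if (is.null(cohort$labels)) stop("cohort has no sample labels")
  if (is.null(subtypes)) subtypes <- sort(unique(cohort$labels))
  sub <- subset_cohort(cohort, probes = nodes)
  out <- matrix("ns", length(nodes), length(subtypes),
                dimnames = list(nodes, subtypes))
  for (st in subtypes) {
    n_case <- sum(cohort$labels == st)
    if (n_case < 2 || ncol(sub$values) - n_case < 2) {
      warning(sprintf("subtype '%s' has < 2 samples; column set to ns", st))
      next
    }
    de <- differential_expression(sub, case_label = st, alpha = alpha)
    out[, st] <- de[nodes, "direction"]
  }
  out
}

#' Separation of sample groups over a probe signature
#'
#' Clusters samples by unsupervised hierarchical clustering with correlation
#' distance (1 - Pearson correlation between sample profiles over the probe
#' signature) and average linkage, cut into `k` clusters, and computes a
#' principal component embedding of the same submatrix. When true labels are
#' available the cluster/label agreement is reported as the adjusted Rand
#' index.
#'
#' @param cohort an [expr_cohort()]; labels (if present) give the agreement
#'   score.
#' @param node_set character vector of probes (the signature), all present
#'   in the cohort.
#' @param k number of clusters to cut; default 2.
#' @return List of class `separation_result`: `cluster` (named integer),
#'   `scores` (samples x PCs), `var_explained` (fractions, non-increasing),
#'   `ari` (adjusted Rand index or `NA` when no labels), `hclust` (the tree).
#' @export
promyelocyte_separation <- function(cohort, node_set, k = 2) {
  stopifnot(inherits(cohort, "expr_cohort"))
  miss <- setdiff(node_set, probe_ids(cohort))
  if (length(miss)) stop("node_set contains probes absent from the cohort")
  if (length(node_set) < 2) stop("need at least 2 probes in node_set")
  v <- cohort$values[node_set, , drop = FALSE]
  if (ncol(v) < k) stop("fewer samples than clusters")
  d <- stats::as.dist(1 - stats::cor(v))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  pca <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  ari <- if (is.null(cohort$labels)) NA_real_ else
    mclust::adjustedRandIndex(cl, cohort$labels[colnames(v)])
  structure(list(cluster = cl, scores = pca$x, var_explained = ve,
                 ari = ari, hclust = hc, k = k),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> %d samples in %d clusters; ARI = %s\n",
              length(x$cluster), x$k,
              ifelse(is.na(x$ari), "NA", sprintf("%.3f", x$ari))))
  cat(sprintf("  PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Build a time-course table of log2 fold changes
#'
#' @param values numeric matrix, genes x timepoints, log2 fold change
#'   relative to the first timepoint (whose column must be identically 0).
#' @param timepoints strictly increasing numeric vector of hours, starting
#'   at the reference time.
#' @return Object of class `time_course`.
#' @export
time_course <- function(values, timepoints) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a gene-named matrix")
  if (length(timepoints) != ncol(values))
    stop("one timepoint per column required")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (any(values[, 1] != 0))
    stop("first timepoint column must be identically 0 (it is the reference)")
  colnames(values) <- as.character(timepoints)
  structure(list(values = values, timepoints = timepoints),
            class = "time_course")
}

#' Read a time-course TSV (first column gene, remaining columns hours)
#' @param path path to the TSV.
#' @return A [time_course()].
#' @export
read_timecourse_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  time_course(m, as.numeric(colnames(m)))
}

#' Expression-reversal score under differentiation treatment
#'
#' Fraction of subnetwork genes whose treatment fold change at `final_time`
#' moves against their disease dysregulation: down-regulated genes with
#' strictly positive log2 fold change plus up-regulated genes with strictly
#' negative fold change, over all subnetwork genes present in the time
#' course (genes with `ns` direction are excluded from both counts).
#'
#' @param tc a [time_course()] of log2 fold changes versus the reference
#'   timepoint.
#' @param subnet an [extract_apl_subnetwork()] result giving per-gene
#'   consensus directions.
#' @param final_time the timepoint (hours) to score; must be present.
#' @return List with `fraction` (in \[0, 1\]) and `table` (data.frame: gene,
#'   direction, fold_change, reversed).
#' @export
atra_reversal <- function(tc, subnet, final_time) {
  stopifnot(inherits(tc, "time_course"), inherits(subnet, "apl_subnetwork"))
  col <- match(as.character(final_time), colnames(tc$values))
  if (is.na(col)) stop("`final_time` not present in the time course")
  dir_by_gene <- tapply(subnet$nodes$direction, subnet$nodes$gene,
                        function(d) {
                          u <- unique(d[d != "ns"])
                          if (length(u) == 1) u else "ns"
                        })
  genes <- intersect(rownames(tc$values), names(dir_by_gene))
  if (!length(genes)) stop("no subnetwork gene present in the time course")
  dir <- dir_by_gene[genes]
  fc <- tc$values[genes, col]
  scored <- dir != "ns"
  reversed <- (dir == "down" & fc > 0) | (dir == "up" & fc < 0)
  frac <- if (any(scored)) sum(reversed[scored]) / sum(scored) else NA_real_
  list(fraction = frac,
       table = data.frame(gene = genes, direction = unname(dir),
                          fold_change = unname(fc),
                          reversed = unname(reversed),
                          stringsAsFactors = FALSE))
}
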