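#' Case-versus-rest differential expression
#'
#' Welch (unequal-variance) two-sample t-test for every probe, comparing the
#' samples of `case_label` against all other samples, with
#' Benjamini-Hochberg FDR adjustment across all tested probes. Directions
#' follow the adjusted p-value: `up` when `q < alpha` and the case mean is
#' higher, `down` when lower, `ns` otherwise.
#'
#' @param cohort a labeled [expr_cohort()] (log2 scale).
#' @param case_label subtype defining the case group.
#' @param alpha FDR level used only to call directions; default 0.05.
#' @return A data.frame of class `diff_expr` with columns `probe`, `t`, `p`,
#'   `q`, `delta` (case mean minus rest mean, log2 units) and `direction`.
#' @export
differential_expression <- function(cohort, case_label = "M3", alpha = 0.05) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (is.null(cohort$labels)) stop("cohort has no sample labels")
  grp <- cohort$labels == case_label
  if (sum(grp) < 2 || sum(!grp) < 2)
    stop(sprintf("need >= 2 samples in '%s' and in the rest", case_label))
  v <- cohort$values
  res <- welch_rows(v[, grp, drop = FALSE], v[, !grp, drop = FALSE])
  q <- stats::p.adjust(res$p, method = "BH")
  direction <- rep("ns", nrow(v))
  direction[q < alpha & res$delta > 0] <- "up"
  direction[q < alpha & res$delta < 0] <- "down"
  out <- data.frame(probe = rownames(v), t = res$t, p = res$p, q = q,
                    delta = res$delta, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$probe
  attr(out, "alpha") <- alpha
  attr(out, "case_label") <- case_label
  class(out) <- c("diff_expr", "data.frame")
  out
}

# Row-wise Welch t-test: x = case matrix, y = rest matrix (same rows).
welch_rows <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  t[se2 == 0] <- 0
  df[se2 == 0] <- nx + ny - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, delta = mx - my)
}

#' Hub table: connectivity versus differential significance
#'
#' One record per network node with its degree and the worst (largest, i.e.
#' least significant) of its two raw cohort p-values — the degree-versus-
#' significance view in which high-degree hubs usually show weak disease
#' differential expression, making jointly high-degree, strongly
#' differential nodes stand out.
#'
#' @param net an `mi_network` (typically the consensus network).
#' @param de_a,de_b [differential_expression()] results for the two cohorts.
#' @param annotation optional probe -> gene map added as a `gene` column.
#' @return data.frame with columns `node`, (`gene`,) `degree`, `worst_p`,
#'   sorted by decreasing degree, ties by node id.
#' @export
hub_table <- function(net, de_a, de_b, annotation = NULL) {
  stopifnot(inherits(net, "mi_network"))
  nodes <- net$nodes
  miss <- setdiff(nodes, intersect(de_a$probe, de_b$probe))
  if (length(miss))
    stop(sprintf("node(s) missing from a differential result: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  deg <- igraph::degree(as_igraph(net))[nodes]
  out <- data.frame(node = nodes,
                    degree = as.integer(deg),
                    worst_p = pmax(de_a[nodes, "p"], de_b[nodes, "p"]),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    out$gene <- unname(annotation[out$node])
    out <- out[, c("node", "gene", "degree", "worst_p")]
  }
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
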