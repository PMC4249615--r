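#' Select case-up-regulated miRNAs
#'
#' Welch t-test per miRNA, case subtype versus all other samples, Bonferroni
#' correction over all tested miRNAs; keeps miRNAs with adjusted p below
#' `alpha` AND a positive mean difference (up-regulated in the case group).
#'
#' @param mirnas an [expr_cohort()] of miRNA expression (log2 scale) with
#'   sample labels.
#' @param case_label subtype defining the case group; default `"M3"`.
#' @param alpha family-wise level after Bonferroni correction; default 0.05.
#' @return data.frame: `mirna`, `t`, `p`, `p_adj`, `delta`, ordered by
#'   adjusted p, containing only the selected miRNAs.
#' @export
select_upregulated_mirnas <- function(mirnas, case_label = "M3",
                                      alpha = 0.05) {
  stopifnot(inherits(mirnas, "expr_cohort"))
  if (is.null(mirnas$labels)) stop("miRNA matrix has no sample labels")
  grp <- mirnas$labels == case_label
  if (sum(grp) < 2 || sum(!grp) < 2)
    stop(sprintf("need >= 2 samples in '%s' and in the rest", case_label))
  v <- mirnas$values
  res <- welch_rows(v[, grp, drop = FALSE], v[, !grp, drop = FALSE])
  p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  out <- data.frame(mirna = rownames(v), t = res$t, p = res$p,
                    p_adj = p_adj, delta = res$delta,
                    stringsAsFactors = FALSE)
  out <- out[out$p_adj < alpha & out$delta > 0, , drop = FALSE]
  out <- out[order(out$p_adj, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank miRNAs by anti-correlation with down-regulated transcripts
#'
#' Pearson correlation between each selected miRNA and each down-regulated
#' subnetwork transcript over the shared samples; (miRNA, transcript) pairs
#' with correlation strictly below `r_threshold` are retained, and miRNAs
#' are ranked by their retained-transcript count (descending, ties by miRNA
#' id). Transcript hits are also collapsed to gene level (a gene counts once
#' if any of its probes passes) for downstream target annotation.
#'
#' @param selected data.frame from [select_upregulated_mirnas()] (or a
#'   character vector of miRNA ids).
#' @param mirnas the miRNA [expr_cohort()].
#' @param cohort the mRNA [expr_cohort()] sharing samples with `mirnas`.
#' @param down_nodes character vector of down-regulated probes.
#' @param annotation named character vector, probe -> gene.
#' @param r_threshold retain pairs with `r < r_threshold` (strict); default
#'   -0.4.
#' @return data.frame of class `anticorrelation_table`: `mirna`,
#'   `n_anticorrelated` (transcript count), `transcripts`, `genes`
#'   (semicolon-joined), ranked as described.
#' @export
anticorrelation_ranking <- function(selected, mirnas, cohort, down_nodes,
                                    annotation, r_threshold = -0.4) {
  stopifnot(inherits(mirnas, "expr_cohort"), inherits(cohort, "expr_cohort"))
  ids <- if (is.data.frame(selected)) selected$mirna else as.character(selected)
  if (!length(ids)) stop("no miRNA selected")
  shared <- intersect(sample_ids(mirnas), sample_ids(cohort))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  down_nodes <- intersect(down_nodes, probe_ids(cohort))
  if (!length(down_nodes)) stop("no down-regulated probe present in the cohort")
  mm <- mirnas$values[ids, shared, drop = FALSE]
  tm <- cohort$values[down_nodes, shared, drop = FALSE]
  r <- stats::cor(t(mm), t(tm))  # miRNAs x transcripts
  rows <- lapply(ids, function(id) {
    hits <- colnames(r)[which(r[id, ] < r_threshold)]
    genes <- sort(unique(unname(annotation[hits])))
    data.frame(mirna = id, n_anticorrelated = length(hits),
               transcripts = paste(sort(hits), collapse = ";"),
               genes = paste(genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_anticorrelated, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anticorrelation_table", "data.frame")
  attr(out, "r_threshold") <- r_threshold
  out
}

#' Read a miRNA-target prediction table
#'
#' Two tab-separated columns, miRNA id and gene symbol; `#` comments
#' allowed. Malformed rows are a hard error reporting the line number.
#'
#' @param path path to the prediction TSV.
#' @return data.frame with columns `mirna` and `gene`.
#' @export
read_predictions_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(rows, function(r) length(r) < 2 || !nzchar(r[1]) ||
                        !nzchar(r[2]), logical(1)))
  if (length(bad))
    stop(sprintf("malformed prediction row at line %d",
                 which(keep)[bad[1]]))
  data.frame(mirna = vapply(rows, `[`, "", 1),
             gene = vapply(rows, `[`, "", 2), stringsAsFactors = FALSE)
}

#' Annotate an anti-correlation table with predicted-target fractions
#'
#' For each miRNA, the fraction of its anti-correlated genes that are also
#' externally predicted targets of that miRNA. An empty anti-correlated
#' list yields `NA` (undefined), never 0.
#'
#' @param table an [anticorrelation_ranking()] result.
#' @param predictions data.frame with columns `mirna`, `gene` (e.g. from
#'   [read_predictions_tsv()]).
#' @return The table with an added `predicted_fraction` column.
#' @export
predicted_target_fraction <- function(table, predictions) {
  stopifnot(inherits(table, "anticorrelation_table"),
            all(c("mirna", "gene") %in% names(predictions)))
  table$predicted_fraction <- vapply(seq_len(nrow(table)), function(i) {
    genes <- strsplit(table$genes[i], ";", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) return(NA_real_)
    targets <- predictions$gene[predictions$mirna == table$mirna[i]]
    length(intersect(genes, targets)) / length(genes)
  }, numeric(1))
  table
}
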