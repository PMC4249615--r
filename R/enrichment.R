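#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields — set name,
#' description, then member gene symbols.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors; the `descriptions` attribute
#'   holds the second field per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad)) stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicated set name in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[`, "", 2), nm)
  sets
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query and the set, drawing the
#' query from the background: `P(X >= k)` with `N` background genes, `K`
#' set genes (after intersection with the background) and `n` query genes.
#' Equivalent to the one-sided Fisher exact test on the 2x2 overlap table.
#'
#' @param query character vector of genes of interest (must be contained in
#'   `background`).
#' @param background character vector, the gene universe (for this pipeline
#'   typically all genes surviving preprocessing).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param correction multiple-testing correction over the tested sets:
#'   `"bh"` (default) or `"bonferroni"`.
#' @return data.frame sorted by adjusted then raw p: `set`, `k` (overlap),
#'   `K` (set size in background), `n` (query size), `N` (background size),
#'   `p`, `p_adj`, `genes` (semicolon-joined overlap).
#' @export
ora_enrichment <- function(query, background, sets,
                           correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  query <- unique(query)
  background <- unique(background)
  if (!length(query)) stop("empty query")
  if (!length(background)) stop("empty background")
  if (!all(query %in% background))
    stop("query genes must be contained in the background")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], background)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(
    out$p, method = if (correction == "bh") "BH" else "bonferroni")
  out <- out[order(out$p_adj, out$p, out$set),
             c("set", "k", "K", "n", "N", "p", "p_adj", "genes")]
  rownames(out) <- NULL
  out
}
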