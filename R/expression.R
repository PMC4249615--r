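#' Expression cohort container
#'
#' A minimal container for one cohort of probe-level expression data: a
#' numeric matrix of probes (rows) by samples (columns) plus an optional
#' per-sample subtype label (FAB class `M0`..`M5`, `PM`, `APL`, ...).
#' Values are raw intensities on input and log2-scale, mean-centered values
#' after [intersect_and_normalize()].
#'
#' @param values numeric matrix, probes x samples, with unique non-empty
#'   rownames (probe ids) and colnames (sample ids); no missing values.
#' @param labels optional character vector of subtype labels, either named by
#'   sample id or in column order.
#' @return An object of class `expr_cohort`: a list with elements `values`
#'   (the matrix) and `labels` (named character vector or `NULL`).
#' @examples
#' m <- matrix(2^rnorm(20), 4, 5,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
#' ec <- expr_cohort(m, labels = rep(c("M3", "M1"), c(2, 3)))
#' ec
#' @export
expr_cohort <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(pid)) stop("duplicated probe ids")
  if (anyDuplicated(sid)) stop("duplicated sample ids")
  if (anyNA(values)) stop("missing values in expression matrix")
  if (!is.null(labels)) {
    labels <- as.character(labels) |> stats::setNames(
      if (is.null(names(labels))) sid else names(labels))
    if (!all(sid %in% names(labels)))
      stop("every sample needs a label when labels are supplied")
    labels <- labels[sid]
  }
  structure(list(values = values, labels = labels), class = "expr_cohort")
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("<expr_cohort> %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expr_cohort <- function(x) dim(x$values)

#' Subset an expression cohort
#'
#' Row (probe) and column (sample) subsetting that keeps labels aligned.
#' @param x an [expr_cohort()].
#' @param probes,samples index vectors (names, logical or integer positions).
#' @param ... unused.
#' @export
subset_cohort <- function(x, probes = NULL, samples = NULL, ...) {
  stopifnot(inherits(x, "expr_cohort"))
  v <- x$values
  if (!is.null(probes)) v <- v[probes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expr_cohort(v, labels = if (is.null(x$labels)) NULL else x$labels[colnames(v)])
}

#' Probe and sample identifiers of a cohort
#' @param x an [expr_cohort()].
#' @return Character vector of ids.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' Expected dialect: a header row of sample ids, first column probe ids,
#' tab-separated numeric values. Missing values are a hard error (no
#' imputation is performed anywhere in the pipeline).
#'
#' @param path path to the TSV file.
#' @param labels optional named character vector of subtype labels (see
#'   [read_labels_tsv()]).
#' @return An [expr_cohort()].
#' @export
read_expression_tsv <- function(path, labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a probe column plus samples")
  pid <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- pid
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at probe '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  expr_cohort(m, labels = labels)
}

#' Read sample subtype labels from TSV
#'
#' Two columns: sample id and subtype label. A header row is tolerated.
#' @param path path to the TSV file.
#' @return Named character vector, sample id -> label.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label TSV needs two columns: sample, subtype")
  if (identical(tolower(df[1, 1]), "sample") ||
      identical(tolower(df[1, 1]), "sample_id"))
    df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read probe-to-gene annotation from TSV
#'
#' Two columns: probe id and gene symbol; several probes may map to the same
#' gene. A header row is tolerated.
#' @param path path to the TSV file.
#' @return Named character vector, probe id -> gene symbol.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation TSV needs two columns: probe, gene")
  if (identical(tolower(df[1, 1]), "probe") ||
      identical(tolower(df[1, 1]), "probe_id"))
    df <- df[-1, , drop = FALSE]
  ann <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (any(!nzchar(ann))) stop("empty gene symbol in annotation")
  if (anyDuplicated(names(ann))) stop("duplicated probe id in annotation")
  ann
}

#' Read a seed gene list
#'
#' Plain text, one gene symbol per line; `#` starts a comment; blank lines
#' are skipped.
#' @param path path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_seed_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("seed list is empty")
  unique(x)
}

#' Resolve seed gene symbols to probe ids
#'
#' Joins a seed gene list against a probe annotation, keeping only probes
#' present in the given cohort.
#'
#' @param genes character vector of seed gene symbols.
#' @param annotation named character vector, probe id -> gene symbol.
#' @param cohort an [expr_cohort()] whose probes bound the resolution.
#' @return A list of class `seed_list` with elements `genes` and `probes`.
#' @export
resolve_seeds <- function(genes, annotation, cohort) {
  stopifnot(inherits(cohort, "expr_cohort"))
  probes <- names(annotation)[annotation %in% genes]
  probes <- intersect(probes, probe_ids(cohort))
  if (!length(probes)) stop("no seed gene resolves to a probe in the matrix")
  structure(list(genes = genes, probes = probes), class = "seed_list")
}
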