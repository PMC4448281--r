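#' Feature-by-sample expression matrix with condition labels
#'
#' Lightweight container for a real-valued matrix whose rows are features
#' (genes, probes) and whose columns are samples, together with a categorical
#' condition label per sample. All feature-extraction functions in the package
#' accept this class (or a bare matrix plus a label vector).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of row identifiers. Defaults to
#'   existing rownames or `feat<i>`.
#' @param sample_ids Character vector of column identifiers. Defaults to
#'   existing colnames or `sample<j>`.
#' @param labels Per-sample class/condition assignment (factor or coercible).
#'   Unordered; one entry per column.
#'
#' @return An object of class `expression_matrix`: the matrix with dimnames
#'   set and the labels attached as a factor attribute.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4),
#'                        labels = c("a", "a", "b", "b"))
#' dim(x)
#' sample_labels(x)
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL,
                              labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (features x samples).")
  if (is.null(feature_ids))
    feature_ids <- rownames(values) %||% paste0("feat", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values) %||% paste0("sample", seq_len(ncol(values)))
  if (length(feature_ids) != nrow(values))
    abort("`feature_ids` length must equal nrow(values).")
  if (length(sample_ids) != ncol(values))
    abort("`sample_ids` length must equal ncol(values).")
  if (is.null(labels)) labels <- rep("all", ncol(values))
  if (length(labels) != ncol(values))
    abort("`labels` must have one entry per sample (column).")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, labels = factor(labels), class = c("expression_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
sample_labels <- function(x) attr(x, "labels")

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples, %d condition(s)\n",
              nrow(x), ncol(x), nlevels(sample_labels(x))))
  invisible(x)
}

## strip class/attrs for plain linear algebra
as_values <- function(x) {
  if (inherits(x, "expression_matrix")) {
    y <- unclass(x)
    attr(y, "labels") <- NULL
    y
  } else as.matrix(x)
}

## resolve (X, labels) from either an expression_matrix or matrix + labels
resolve_labels <- function(x, labels = NULL) {
  if (is.null(labels)) {
    if (!inherits(x, "expression_matrix"))
      abort("`labels` must be supplied when `x` is a bare matrix.")
    labels <- sample_labels(x)
  }
  if (length(labels) != ncol(x))
    abort("label/sample length mismatch.")
  factor(labels)
}

#' Read and write expression matrices as tab-delimited text
#'
#' The on-disk layout is the one microarray supplements use: features in
#' rows, a header row of sample identifiers, and (optionally) a two-column
#' sample-to-condition map alongside.
#'
#' @param x An `expression_matrix`.
#' @param path Path of the matrix TSV.
#' @param map_path Optional path for the two-column (`sample_id`,
#'   `condition`) map; written/read when non-`NULL`.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an `expression_matrix`.
#' @export
write_expression <- function(x, path, map_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = rownames(x), as_values(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    map <- data.frame(sample_id = colnames(x),
                      condition = as.character(sample_labels(x)))
    write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, map_path = NULL) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  labels <- NULL
  if (!is.null(map_path)) {
    map <- read.delim(map_path)
    labels <- map$condition[match(colnames(values), map$sample_id)]
    if (anyNA(labels)) abort("condition map does not cover every sample.")
  }
  expression_matrix(values, labels = labels)
}
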