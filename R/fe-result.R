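#' Feature-extraction result
#'
#' All FE methods return an `fe_result`: a tibble with one row per feature,
#' ordered by the method's ranking, carrying the per-feature score (a
#' statistic, HSIC contribution, or P-value), adjusted P-values where the
#' method uses them, and a `selected` flag. The selected indices (in rank
#' order) are available through [selected_features()].
#'
#' @param table Tibble with at least `feature`, `feature_id`, `score`,
#'   `selected` columns, ordered by rank.
#' @param method Method name.
#' @param params Named list of method parameters.
#' @return An `fe_result` tibble.
#' @keywords internal
fe_result <- function(table, method, params = list()) {
  table$rank <- seq_len(nrow(table))
  out <- as_tibble(table)
  attr(out, "method") <- method
  attr(out, "params") <- params
  class(out) <- c("fe_result", class(out))
  out
}

#' @rdname fe_result
#' @param x An `fe_result`.
#' @export
selected_features <- function(x) {
  stopifnot(inherits(x, "fe_result"))
  x$feature[x$selected]
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("fe_result [%s]: %d/%d features selected\n",
              attr(x, "method"), sum(x$selected), nrow(x)))
  NextMethod()
}

#' @exportS3Method
tidy.fe_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fe_result")
  out
}

#' @exportS3Method
glance.fe_result <- function(x, ...) {
  tibble(method = attr(x, "method"),
         n_features = nrow(x),
         n_selected = sum(x$selected))
}
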