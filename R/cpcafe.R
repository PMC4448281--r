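#' Embed features into principal-component space
#'
#' Computes the factorization \eqn{X \approx B A^T} of the (optionally
#' preprocessed) feature-by-sample matrix via SVD: `feature_scores`
#' `B = U D` are the feature projections (each feature is a point in PC
#' space) and `sample_loadings` `A = V` are orthonormal per-sample
#' contributions to each PC. This is the embedding CPCAFE selects outliers
#' from, and the same convention VBPCA is initialized with.
#'
#' Preprocessing, in order: `standardize_features` shifts/scales each
#' feature row to mean 0, sd 1 (the mRNA preprocessing of the real-data
#' pipeline); then `center` removes per-sample column means (`"sample"`,
#' the default), per-feature row means (`"feature"`), or nothing
#' (`"none"`, the convention for the simulation benchmark where the
#' simulated values are used exactly as produced). The applied record is
#' kept in `preprocessing` so runs are self-describing. Each PC's sign is
#' fixed so the largest-magnitude entry of its sample loading is positive
#' (selection uses absolute scores, so results do not depend on this).
#'
#' @param x An [expression_matrix()] or numeric matrix (features x
#'   samples), no missing values.
#' @param standardize_features Standardize feature rows first?
#' @param center Column/row centering applied after standardization.
#' @param Q Number of components to keep (default `min(N, M)`).
#' @return A `pca_embedding`: list with `feature_scores` (`N x Q`),
#'   `sample_loadings` (`M x Q`, orthonormal columns), `explained`
#'   (per-PC variance shares), `preprocessing`, `feature_ids`,
#'   `sample_ids`.
#' @export
pca_embed <- function(x, standardize_features = FALSE,
                      center = c("sample", "feature", "none"), Q = NULL) {
  center <- match.arg(center)
  X <- as_values(x)
  if (anyNA(X)) abort("missing values are not supported.")
  raw_sample_means <- colMeans(X)
  if (standardize_features) {
    sds <- apply(X, 1, sd)
    if (any(sds == 0)) {
      bad <- rownames(X)[sds == 0] %||% which(sds == 0)
      abort(paste0("zero-variance feature(s) under standardization: ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    X <- (X - rowMeans(X)) / sds
  }
  if (center == "sample") X <- sweep(X, 2, colMeans(X))
  if (center == "feature") X <- X - rowMeans(X)
  if (is.null(Q)) Q <- min(dim(X))
  sv <- svd(X, nu = Q, nv = Q)
  d <- sv$d[seq_len(Q)]
  ## sign convention: largest |entry| of each sample loading positive
  flip <- vapply(seq_len(Q), function(q) {
    v <- sv$v[, q]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  B <- sweep(sv$u, 2, d * flip, "*")
  A <- sweep(sv$v, 2, flip, "*")
  structure(list(
    feature_scores = B, sample_loadings = A,
    explained = sv$d^2 / sum(sv$d^2),
    preprocessing = list(standardize_features = standardize_features,
                         center = center),
    sample_means = raw_sample_means,
    feature_ids = rownames(X) %||% as.character(seq_len(nrow(X))),
    sample_ids = colnames(X) %||% as.character(seq_len(ncol(X)))),
    class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf(
    "pca_embedding: %d features x %d samples, %d PCs (PC1 %.1f%% variance)\n",
    nrow(x$feature_scores), nrow(x$sample_loadings),
    ncol(x$feature_scores), 100 * x$explained[1]))
  invisible(x)
}

#' CPCAFE: select outlier features along a principal component
#'
#' Conventional-PCA-based unsupervised feature extraction: the `n_top`
#' features with the largest absolute projection \eqn{|B_{i,pc}|} on the
#' chosen PC are returned, in descending order. Optionally, features whose
#' absolute score on another PC exceeds a quantile threshold are excluded
#' first (used on real data to drop probes dominated by a nuisance
#' component).
#'
#' @param emb A [pca_embed()] result.
#' @param pc PC index used for selection.
#' @param n_top Number of features to select.
#' @param exclude_pc Optional PC index for prior exclusion.
#' @param exclude_quantile Quantile of `|score|` on `exclude_pc` above
#'   which features are excluded (default 0.99).
#' @param exclude_features Optional explicit feature indices to drop first
#'   (e.g. known erroneous probes).
#' @return An [fe_result]; `score` is \eqn{|B_{i,pc}|}.
#' @export
cpcafe_select <- function(emb, pc = 1, n_top = 10, exclude_pc = NULL,
                          exclude_quantile = 0.99,
                          exclude_features = NULL) {
  stopifnot(inherits(emb, "pca_embedding"))
  B <- emb$feature_scores
  if (pc > ncol(B)) abort("pc exceeds the number of components.")
  if (n_top > nrow(B)) abort("n_top exceeds feature count.")
  keep <- setdiff(seq_len(nrow(B)), exclude_features)
  if (!is.null(exclude_pc)) {
    if (exclude_pc > ncol(B)) abort("exclude_pc exceeds component count.")
    a <- abs(B[keep, exclude_pc])
    keep <- keep[a <= quantile(a, exclude_quantile)]
  }
  if (length(keep) < n_top)
    abort("fewer than n_top features survive exclusion.")
  sc <- abs(B[keep, pc])
  ord <- keep[order(-sc, keep)]
  fe_result(tibble(feature = ord,
                   feature_id = emb$feature_ids[ord],
                   score = abs(B[ord, pc]),
                   selected = seq_along(ord) <= n_top),
            method = "cpcafe",
            params = list(pc = pc, n_top = n_top, exclude_pc = exclude_pc,
                          exclude_quantile = exclude_quantile))
}

#' @exportS3Method
tidy.pca_embedding <- function(x, ...) {
  out <- tibble(feature_id = x$feature_ids)
  for (q in seq_len(ncol(x$feature_scores)))
    out[[paste0("PC", q)]] <- x$feature_scores[, q]
  out
}

#' @exportS3Method
glance.pca_embedding <- function(x, ...) {
  tibble(n_features = nrow(x$feature_scores),
         n_samples = nrow(x$sample_loadings),
         n_components = ncol(x$feature_scores),
         pc1_explained = x$explained[1])
}

#' Scatterplot of the feature embedding
#'
#' Features as points in the plane of two PCs, optionally highlighting a
#' selected set — the standard diagnostic view for PC-outlier selection.
#'
#' @param object A `pca_embedding`.
#' @param pcs Length-2 integer vector of PCs to plot.
#' @param highlight Optional feature indices drawn in color.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.pca_embedding <- function(object, pcs = c(1, 2),
                                   highlight = NULL, ...) {
  df <- tibble(x = object$feature_scores[, pcs[1]],
               y = object$feature_scores[, pcs[2]],
               highlighted = seq_len(nrow(object$feature_scores)) %in%
                 (highlight %||% integer(0)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$highlighted)) +
    ggplot2::geom_point(alpha = 0.7, show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = paste0("PC", pcs[1], " feature score"),
                  y = paste0("PC", pcs[2], " feature score"),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
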