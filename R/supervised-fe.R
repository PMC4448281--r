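#' One-vs-one t-test feature extraction
#'
#' For each feature and each of the `K(K-1)/2` class pairs, a two-sample
#' Welch t test is computed; P-values are BH-adjusted (by default jointly
#' over all features and pairs) and a feature is selected iff its adjusted P
#' is below `alpha` for *every* pair. On weakly separated multiclass data
#' this criterion is extremely conservative — adjacent-class contrasts
#' rarely reach significance — which is exactly the failure mode the
#' unsupervised methods in this package address.
#'
#' @param x An [expression_matrix()] or numeric matrix (features x samples).
#' @param labels Per-sample class labels (taken from `x` if omitted).
#' @param alpha Significance level on adjusted P-values.
#' @param adjust_scope `"joint"` (one BH adjustment over all `N * K(K-1)/2`
#'   P-values, default) or `"per_pair"` (BH within each class pair).
#' @return An [fe_result] ranked by the feature's worst (largest) adjusted
#'   pairwise P-value; `score` is that worst adjusted P.
#' @export
ttest_ovo_fe <- function(x, labels = NULL, alpha = 0.05,
                         adjust_scope = c("joint", "per_pair")) {
  adjust_scope <- match.arg(adjust_scope)
  labels <- resolve_labels(x, labels)
  X <- as_values(x)
  if (any(tabulate(labels) < 2))
    abort("every class must have at least 2 samples.")
  K <- nlevels(labels)
  pairs <- utils::combn(K, 2)
  pmat <- apply(pairs, 2, function(kk) {
    ja <- which(as.integer(labels) == kk[1])
    jb <- which(as.integer(labels) == kk[2])
    welch_t_rows(X[, ja, drop = FALSE], X[, jb, drop = FALSE])$p_two
  })
  pmat <- matrix(pmat, nrow = nrow(X))
  adj <- if (adjust_scope == "joint") {
    matrix(p.adjust(pmat, method = "BH"), nrow = nrow(X))
  } else {
    apply(pmat, 2, p.adjust, method = "BH")
  }
  worst <- apply(adj, 1, max)
  ord <- order(worst, seq_len(nrow(X)))
  fe_result(tibble(feature = ord,
                   feature_id = rownames(X)[ord] %||% as.character(ord),
                   score = worst[ord],
                   selected = worst[ord] < alpha),
            method = "ttest",
            params = list(alpha = alpha, adjust_scope = adjust_scope))
}

## row-wise Welch t between two sample groups; returns t, df, two-sided p
welch_t_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tt, df = df, p_two = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

#' Categorical regression feature extraction
#'
#' Regresses each feature on class-membership dummy variables,
#' \eqn{x_{ij} = C_{i0} + \sum_k C_{ik} \delta_{jk}}, and ranks features by
#' the overall model-significance P-value — identical to the one-way ANOVA
#' F test across classes. `mode = "adjusted"` selects features with
#' BH-adjusted P below `alpha`; `mode = "ranked"` selects the `n_top`
#' smallest P-values regardless of significance (ties broken by larger F,
#' then lower index).
#'
#' Zero-variance (constant) features get P = 1 so they never outrank an
#' informative feature.
#'
#' @inheritParams ttest_ovo_fe
#' @param mode `"adjusted"` or `"ranked"`.
#' @param n_top Selection size for `mode = "ranked"`.
#' @return An [fe_result] with `score` = F statistic, `p_value` and
#'   `adj_p` columns, ranked by (P, -F, index).
#' @export
categorical_regression_fe <- function(x, labels = NULL,
                                      mode = c("adjusted", "ranked"),
                                      alpha = 0.05, n_top = 10) {
  mode <- match.arg(mode)
  labels <- resolve_labels(x, labels)
  X <- as_values(x)
  if (nlevels(labels) < 2) abort("at least 2 classes required.")
  if (any(tabulate(labels) == 0)) abort("each class must be nonempty.")
  an <- anova_f_rows(X, labels)
  adj <- p.adjust(an$p, method = "BH")
  ord <- order(an$p, -an$f, seq_len(nrow(X)))
  selected <- if (mode == "adjusted") {
    adj[ord] < alpha
  } else {
    if (n_top > nrow(X)) abort("n_top exceeds feature count.")
    seq_len(nrow(X)) <= n_top
  }
  fe_result(tibble(feature = ord,
                   feature_id = rownames(X)[ord] %||% as.character(ord),
                   score = an$f[ord],
                   p_value = an$p[ord],
                   adj_p = adj[ord],
                   selected = selected),
            method = paste0("catreg-", substr(mode, 1, 3)),
            params = list(mode = mode, alpha = alpha, n_top = n_top))
}

## vectorized one-way ANOVA F across rows
anova_f_rows <- function(X, labels) {
  K <- nlevels(labels); M <- ncol(X)
  idx <- split(seq_len(M), labels)
  n <- lengths(idx)
  gm <- vapply(idx, function(j) rowMeans(X[, j, drop = FALSE]),
               numeric(nrow(X)))
  gm <- matrix(gm, nrow = nrow(X))
  overall <- rowMeans(X)
  ssb <- rowSums(sweep(gm, 2, n, "*") * gm) - M * overall^2
  sst <- rowSums(X^2) - M * overall^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (K - 1)) / (ssw / (M - K))
  p <- pf(f, K - 1, M - K, lower.tail = FALSE)
  zerovar <- sst <= .Machine$double.eps * M * pmax(rowMeans(X^2), 1)
  p[zerovar] <- 1
  f[zerovar] <- 0
  list(f = f, p = p)
}

#' Hilbert-Schmidt independence criterion (linear kernel, delta labels)
#'
#' Computes the (biased, uniformly averaged over all sample pairs including
#' the diagonal) HSIC between a feature subset and class labels:
#' \deqn{HSIC = \frac{1}{M^2} \mathrm{tr}(K H L H),}
#' with the linear data kernel \eqn{K_{jj'} = \sum_i x_{ij} x_{ij'}}, the
#' delta label kernel \eqn{L_{jj'} = 1} iff the labels agree, and the
#' centering matrix \eqn{H = I - \mathbf{1}\mathbf{1}^T/M}. Equivalent to
#' the three-term mean form \eqn{\langle KL\rangle + \langle K\rangle\langle
#' L\rangle - 2\langle \langle K\rangle_{j''} \langle L\rangle_{j'''}
#' \rangle}. For the linear kernel HSIC is additive over features, which
#' [per_feature_hsic()] exploits.
#'
#' @param x Numeric matrix (features x samples), a single-feature vector, or
#'   an [expression_matrix()].
#' @param labels Per-sample labels.
#' @return Nonnegative scalar HSIC value.
#' @export
hsic <- function(x, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  labels <- resolve_labels(x, labels)
  sum(per_feature_hsic(x, labels))
}

#' @rdname hsic
#' @return `per_feature_hsic`: vector of per-feature HSIC contributions
#'   (single-feature linear-kernel HSIC values; their sum is [hsic()]).
#' @export
per_feature_hsic <- function(x, labels = NULL) {
  labels <- resolve_labels(x, labels)
  X <- as_values(x)
  M <- ncol(X)
  if (M < 2) abort("at least 2 samples required.")
  L <- outer(labels, labels, "==") * 1
  H <- diag(M) - 1 / M
  S <- H %*% L %*% H
  rowSums((X %*% S) * X) / M^2
}

#' BAHSIC backward elimination
#'
#' Iteratively discards the features contributing least to the
#' linear-kernel HSIC between the remaining feature set and the labels,
#' until `n_target` features remain. The drop rule removes either a fixed
#' count per step (1 for the simulation benchmark) or a fraction of the
#' remaining features (10% for large real data); the final batch is trimmed
#' to land on `n_target` exactly. Per-feature contributions are recomputed
#' on the remaining set at every step, preserving the elimination schedule
#' (under the linear kernel the contributions are additive, so ranks are
#' static — the schedule is kept for fidelity to the algorithm).
#'
#' @inheritParams ttest_ovo_fe
#' @param n_target Number of features to retain (`>= 1`).
#' @param drop_count Features removed per step (used when `drop_fraction`
#'   is `NULL`).
#' @param drop_fraction If set, fraction of remaining features removed per
#'   step.
#' @return An [fe_result] ordered by elimination order, last-surviving
#'   first; survivors are `selected`, `score` is the per-feature HSIC at
#'   the step the feature left (or the final step for survivors).
#' @export
bahsic_select <- function(x, labels = NULL, n_target = 10, drop_count = 1,
                          drop_fraction = NULL) {
  labels <- resolve_labels(x, labels)
  X <- as_values(x)
  N <- nrow(X)
  if (n_target <= 0) abort("n_target must be positive.")
  if (n_target > N) abort("n_target must be <= feature count.")
  remaining <- seq_len(N)
  eliminated <- integer(0)
  elim_score <- numeric(0)
  h <- per_feature_hsic(X, labels)
  while (length(remaining) > n_target) {
    h <- per_feature_hsic(X[remaining, , drop = FALSE], labels)
    batch <- if (is.null(drop_fraction)) drop_count
             else max(1L, floor(drop_fraction * length(remaining)))
    batch <- min(batch, length(remaining) - n_target)
    drop <- order(h, seq_along(h))[seq_len(batch)]
    eliminated <- c(eliminated, remaining[drop])
    elim_score <- c(elim_score, h[drop])
    remaining <- remaining[-drop]
  }
  h_final <- per_feature_hsic(X[remaining, , drop = FALSE], labels)
  surv_ord <- order(-h_final, seq_along(h_final))
  ord <- c(remaining[surv_ord], rev(eliminated))
  score <- c(h_final[surv_ord], rev(elim_score))
  fe_result(tibble(feature = ord,
                   feature_id = rownames(X)[ord] %||% as.character(ord),
                   score = score,
                   selected = seq_along(ord) <= length(remaining)),
            method = "bahsic",
            params = list(n_target = n_target, drop_count = drop_count,
                          drop_fraction = drop_fraction))
}
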