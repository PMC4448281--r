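#' Feature-dependent variational Bayes PCA (VBPCAFE)
#'
#' Fits the low-rank model \eqn{X = B A^T + E} (`B`: `N x Q` feature
#' scores, `A`: `M x Q` sample loadings, Gaussian noise with variance
#' \eqn{\sigma_E^2}) by variational Bayes, with a *feature-dependent* prior
#' variance on each feature score, \eqn{P(B_{iq}) \propto
#' \exp\{-B_{iq}^2 / (2 C_B^{iq})\}}. The converged \eqn{C_B^{iq}} performs
#' automatic relevance determination per feature: features relevant to
#' component `q` keep a large prior variance, irrelevant ones are pruned
#' towards zero. Feature extraction reads off the largest \eqn{C_B^{i1}}.
#' Divergence of the component-level scale is suppressed by normalizing the
#' component relevance \eqn{C_A} to sum to one each cycle.
#'
#' `vbpca_init()` seeds the iteration from a truncated SVD of `X` (the
#' factorization \eqn{X \approx B A^T} with `B = U D`, `A = V`), which
#' substitutes pre-computed principal components and compensates for slow
#' convergence.
#'
#' @param x An [expression_matrix()] or numeric matrix (features x
#'   samples). Used exactly as given; no centering is applied.
#' @param Q Latent dimension (`<= min(N, M)`).
#' @return `vbpca_init`: a `vbpca_state` list with elements `A_hat`
#'   (`M x Q`), `B_hat` (`N x Q`), `Sigma_A` (`Q x Q`), `Sigma_B`
#'   (`Q x Q x N` array of per-feature covariances), `C_A` (length-`Q`
#'   relevance, sums to 1), `C_B` (`N x Q` per-feature prior variances),
#'   `sigma_E2`, `F` (free energy, `NA` until evaluated), `Q`, `iter`.
#' @export
vbpca_init <- function(x, Q) {
  X <- as_values(x)
  N <- nrow(X); M <- ncol(X)
  if (Q > min(N, M)) abort("Q must be <= min(N, M).")
  sv <- svd(X, nu = Q, nv = Q)
  d <- sv$d[seq_len(Q)]
  B <- sv$u %*% diag(d, Q)
  A <- sv$v
  state <- list(
    A_hat = A, B_hat = B,
    Sigma_A = diag(1e-6, Q),
    Sigma_B = array(diag(1e-6, Q), dim = c(Q, Q, N)),
    C_A = rep(1 / Q, Q),
    C_B = B^2 + 1e-6,
    sigma_E2 = max(sum((X - B %*% t(A))^2) / (N * M), 1e-12),
    F = NA_real_, Q = Q, iter = 0L)
  class(state) <- "vbpca_state"
  state
}

#' @export
print.vbpca_state <- function(x, ...) {
  cat(sprintf("vbpca_state: N = %d, M = %d, Q = %d, iter = %d, F = %s\n",
              nrow(x$B_hat), nrow(x$A_hat), x$Q, x$iter,
              format(x$F, digits = 8)))
  invisible(x)
}

## floor for prior variances and noise variance before inversion; dead
## features driven to ~0 by ARD would otherwise make C_B^-1 singular
.vb_floor <- 1e-12

## solve with a one-shot ridge retry on numerical singularity
solve_ridged <- function(m) {
  tryCatch(solve(m), error = function(e) {
    solve(m + diag(1e-10, nrow(m)))
  })
}

#' One full VBPCA update cycle
#'
#' Applies, in order: the sample-loading covariance and mean updates
#' (\eqn{\Sigma_A}, \eqn{\hat A}), the per-feature score covariance and
#' mean updates (\eqn{\Sigma_B^i}, \eqn{\hat B_i}), the normalized
#' component relevance \eqn{C_A}, the per-feature relevance
#' \eqn{C_B^{iq} = B_{iq}^2 + (\Sigma_B^i)_{qq}}, and the noise variance
#' \eqn{\sigma_E^2} (the expected mean squared residual). The update order
#' is fixed for reproducibility.
#'
#' @param state A `vbpca_state`.
#' @param x The data matrix the state is being fitted to.
#' @return The updated `vbpca_state` (free energy not re-evaluated; see
#'   [free_energy()]).
#' @export
vbpca_update <- function(state, x) {
  V <- as_values(x)
  N <- nrow(V); M <- ncol(V); Q <- state$Q
  s2 <- max(state$sigma_E2, .vb_floor)
  B <- state$B_hat
  SigB <- state$Sigma_B
  CB <- pmax(state$C_B, .vb_floor)

  sum_SigB <- apply(SigB, c(1, 2), sum)
  Sigma_A <- s2 * solve_ridged(crossprod(B) + sum_SigB +
                                 s2 * diag(1 / state$C_A, Q))
  A <- t(V) %*% B %*% Sigma_A / s2

  G <- crossprod(A) + M * Sigma_A
  VA <- V %*% A
  for (i in seq_len(N)) {
    SigB[, , i] <- s2 * solve_ridged(G + s2 * diag(1 / CB[i, ], Q))
    B[i, ] <- (VA[i, ] %*% SigB[, , i]) / s2
  }

  C_A_tilde <- colSums(A^2) / M + diag(Sigma_A)
  C_A <- C_A_tilde / sum(C_A_tilde)
  diag_SigB <- matrix(apply(SigB, 3, diag), nrow = N, byrow = TRUE)
  C_B <- B^2 + diag_SigB

  sum_SigB <- apply(SigB, c(1, 2), sum)
  G <- crossprod(A) + M * Sigma_A
  s2_new <- (sum(V^2) - 2 * sum(VA * B) +
               sum(G * (crossprod(B) + sum_SigB))) / (N * M)

  state$A_hat <- A; state$B_hat <- B
  state$Sigma_A <- Sigma_A; state$Sigma_B <- SigB
  state$C_A <- C_A; state$C_B <- C_B
  state$sigma_E2 <- max(s2_new, .vb_floor)
  state$iter <- state$iter + 1L
  state$F <- NA_real_
  state
}

#' Variational free energy of a VBPCA state
#'
#' The objective the updates descend (an additive constant is dropped):
#' \deqn{F = \frac{\|V\|_F^2}{2\sigma_E^2} + \frac{NM}{2}\log\sigma_E^2
#'   + \frac{M}{2}\log\frac{|C_A|}{|\Sigma_A|}
#'   + \frac12\sum_i \log\frac{|C_B^i|}{|\Sigma_B^i|}
#'   + \frac12\sum_i \hat B_i^T (C_B^i)^{-1} \hat B_i
#'   + \frac12 \mathrm{tr}\{\dots\}}
#' with the trace collecting the prior and likelihood cross terms (see the
#' vignette). The minimum-`F` state visited during a fit is the one
#' reported.
#'
#' @inheritParams vbpca_update
#' @return Scalar free energy.
#' @export
free_energy <- function(state, x) {
  V <- as_values(x)
  N <- nrow(V); M <- ncol(V); Q <- state$Q
  s2 <- state$sigma_E2
  if (s2 <= 0) abort("sigma_E2 must be positive.")
  A <- state$A_hat; B <- state$B_hat
  Sigma_A <- state$Sigma_A; SigB <- state$Sigma_B
  CB <- pmax(state$C_B, .vb_floor)
  ld_Sigma_A <- determinant(Sigma_A, logarithm = TRUE)$modulus
  if (!is.finite(ld_Sigma_A)) abort("Sigma_A is not positive-definite.")
  ld_SigB <- vapply(seq_len(N), function(i) {
    m <- determinant(SigB[, , i], logarithm = TRUE)
    as.numeric(m$modulus)
  }, numeric(1))
  diag_SigB <- matrix(apply(SigB, 3, diag), nrow = N, byrow = TRUE)
  sum_SigB <- apply(SigB, c(1, 2), sum)
  G <- crossprod(A) + M * Sigma_A
  sum(V^2) / (2 * s2) + N * M / 2 * log(s2) +
    M / 2 * (sum(log(state$C_A)) - as.numeric(ld_Sigma_A)) +
    0.5 * (sum(log(CB)) - sum(ld_SigB)) +
    0.5 * sum(B^2 / CB) +
    0.5 * (sum(G * diag(1 / state$C_A, Q)) +
             sum(diag_SigB / CB) +
             (1 / s2) * (-2 * sum((V %*% A) * B) +
                           sum(G * (crossprod(B) + sum_SigB))))
}

#' Fit VBPCAFE to convergence
#'
#' Runs [vbpca_update()] cycles from a [vbpca_init()] start, evaluating the
#' free energy and the current top-`n_top` feature set by \eqn{C_B^{i1}}
#' after each cycle. Convergence is declared when the extracted set has not
#' changed for more than `patience` consecutive iterations (default 100);
#' the state with the smallest free energy visited is returned.
#'
#' @inheritParams vbpca_init
#' @param n_top Size of the tracked extracted set.
#' @param max_iter Iteration cap (`>= patience`).
#' @param patience Consecutive unchanged-set iterations required.
#' @return The minimum-free-energy `vbpca_state`, with attributes
#'   `converged` (logical), `iterations` (cycles run) and `F_trace`
#'   (free energy per iteration).
#' @export
vbpca_fit <- function(x, Q = 10, n_top = 10, max_iter = 1000,
                      patience = 100) {
  if (max_iter < 1) abort("max_iter must be >= 1.")
  if (patience < 1) abort("patience must be >= 1.")
  if (max_iter < patience) abort("max_iter must be >= patience.")
  X <- as_values(x)
  state <- vbpca_init(X, Q)
  best <- NULL; best_F <- Inf
  last_set <- integer(0); stable <- 0L; converged <- FALSE
  F_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    state <- vbpca_update(state, X)
    Fv <- free_energy(state, X)
    if (!is.finite(Fv))
      abort(sprintf("free energy diverged at iteration %d.", it))
    state$F <- Fv
    F_trace <- c(F_trace, Fv)
    if (Fv < best_F) { best_F <- Fv; best <- state }
    sel <- sort(order(state$C_B[, 1], decreasing = TRUE)[seq_len(n_top)])
    if (identical(sel, last_set)) {
      stable <- stable + 1L
    } else {
      stable <- 0L
      last_set <- sel
    }
    if (stable > patience) { converged <- TRUE; break }
  }
  attr(best, "converged") <- converged
  attr(best, "iterations") <- state$iter
  attr(best, "F_trace") <- F_trace
  best
}

#' Extract features from a fitted VBPCA state
#'
#' Returns the `n_top` features with the largest feature-dependent prior
#' variance \eqn{C_B^{iq}} on component `q`, in descending order. At
#' convergence \eqn{C_B^{i1}} is quadratically dependent on the feature
#' score \eqn{B_{i1}}, which is why this selection agrees with
#' conventional-PCA outlier selection ([cpcafe_select()]).
#'
#' @param state A fitted `vbpca_state`.
#' @param q Component index (1-based).
#' @param n_top Number of features to extract.
#' @param feature_ids Optional feature identifiers.
#' @return An [fe_result]; `score` is \eqn{C_B^{iq}}.
#' @export
vbpcafe_select <- function(state, q = 1, n_top = 10, feature_ids = NULL) {
  stopifnot(inherits(state, "vbpca_state"))
  N <- nrow(state$C_B)
  if (q < 1 || q > state$Q) abort("q must be in 1..Q.")
  if (n_top > N) abort("n_top exceeds feature count.")
  cb <- state$C_B[, q]
  ord <- order(cb, decreasing = TRUE)
  if (is.null(feature_ids)) feature_ids <- as.character(seq_len(N))
  fe_result(tibble(feature = ord,
                   feature_id = feature_ids[ord],
                   score = cb[ord],
                   selected = seq_len(N) <= n_top),
            method = "vbpcafe",
            params = list(q = q, n_top = n_top))
}

#' @exportS3Method
tidy.vbpca_state <- function(x, ...) {
  N <- nrow(x$C_B)
  out <- tibble(feature = seq_len(N))
  for (q in seq_len(x$Q)) {
    out[[paste0("B", q)]] <- x$B_hat[, q]
    out[[paste0("C_B", q)]] <- x$C_B[, q]
  }
  out
}

#' @exportS3Method
glance.vbpca_state <- function(x, ...) {
  tibble(Q = x$Q, sigma_E2 = x$sigma_E2, F = x$F,
         iterations = attr(x, "iterations") %||% x$iter,
         converged = attr(x, "converged") %||% NA)
}
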