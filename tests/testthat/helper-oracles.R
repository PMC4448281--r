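## Independent oracles used across the suite. Each re-derives a quantity by
## a different route than the package implementation.

## HSIC by the literal three-term mean form (uniform averages over all
## sample pairs, diagonal included); the package uses the centered-Gram
## trace instead.
oracle_hsic_three_term <- function(X, labels) {
  M <- ncol(X)
  K <- crossprod(X) # K[j, j'] = sum_i x_ij x_ij'
  L <- outer(labels, labels, "==") * 1
  mean(K * L) + mean(K) * mean(L) - 2 * mean(rowMeans(K) * rowMeans(L))
}

## MCC as the Pearson correlation of binary selection/truth indicators.
oracle_mcc_cor <- function(TP, TN, FP, FN) {
  sel <- c(rep(1, TP), rep(0, FN), rep(1, FP), rep(0, TN))
  tru <- c(rep(1, TP), rep(1, FN), rep(0, FP), rep(0, TN))
  r <- suppressWarnings(cor(sel, tru))
  if (is.na(r)) 0 else r
}

## F as the harmonic mean of precision and recall.
oracle_f_harmonic <- function(TP, TN, FP, FN) {
  if (TP == 0) return(0)
  prec <- TP / (TP + FP)
  rec <- TP / (TP + FN)
  2 * prec * rec / (prec + rec)
}

## Benjamini-Hochberg by the step-up definition.
oracle_bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

## 7mer-m8 matching by scanning every 7-mer window of the UTR.
oracle_seed_scan <- function(mirna_seq, utr_seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  seed <- strsplit(toupper(mirna_seq), "")[[1]][2:8]
  site <- paste(rev(unname(comp[seed])), collapse = "")
  if (anyNA(comp[seed])) return(integer(0))
  utr <- toupper(utr_seq)
  n <- nchar(utr)
  hits <- integer(0)
  for (off in 0:(n - 7)) {
    if (substr(utr, off + 1, off + 7) == site) hits <- c(hits, off)
  }
  hits
}

## free energy transcribed literally term by term (loops, no shared
## intermediates with the package implementation)
oracle_free_energy <- function(state, V) {
  N <- nrow(V); M <- ncol(V); Q <- state$Q
  s2 <- state$sigma_E2
  A <- state$A_hat; B <- state$B_hat
  term1 <- sum(V^2) / (2 * s2)
  term2 <- (N * M / 2) * log(s2)
  term3 <- (M / 2) * log(prod(state$C_A) / det(state$Sigma_A))
  term4 <- 0
  term5 <- 0
  for (i in seq_len(N)) {
    CBi <- pmax(state$C_B[i, ], 1e-12)
    term4 <- term4 + 0.5 * log(prod(CBi) / det(state$Sigma_B[, , i]))
    term5 <- term5 + 0.5 * sum(B[i, ]^2 / CBi)
  }
  G <- t(A) %*% A + M * state$Sigma_A
  tr1 <- sum(diag(diag(1 / state$C_A, Q) %*% G))
  tr2 <- 0
  sumSB <- matrix(0, Q, Q)
  for (i in seq_len(N)) {
    CBi <- pmax(state$C_B[i, ], 1e-12)
    tr2 <- tr2 + sum(diag(diag(1 / CBi, Q) %*% state$Sigma_B[, , i]))
    sumSB <- sumSB + state$Sigma_B[, , i]
  }
  BtB <- t(B) %*% B
  tr3 <- (1 / s2) * (-2 * sum(diag(t(A) %*% t(V) %*% B)) +
                       sum(diag(G %*% (BtB + sumSB))))
  term1 + term2 + term3 + term4 + term5 + 0.5 * (tr1 + tr2 + tr3)
}

## small random multiclass matrix for property loops
random_labeled_matrix <- function(N, M, K, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(N * M), N, M),
       labels = factor(rep_len(seq_len(K), M)))
}
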