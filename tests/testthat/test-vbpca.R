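planted_rank1 <- function(N = 100, n_sig = 10, M = 20, amp = 3, seed = 1) {
  set.seed(seed)
  u <- c(rep(1, n_sig), rep(0, N - n_sig))
  v <- rnorm(M)
  amp * outer(u, v) + matrix(rnorm(N * M, 0, 0.5), N, M)
}

test_that("initialization reproduces a low-rank matrix exactly", {
  set.seed(2)
  B0 <- matrix(rnorm(30), 10, 3)
  A0 <- matrix(rnorm(18), 6, 3)
  X <- B0 %*% t(A0) # exactly rank 3
  st <- vbpca_init(X, Q = 3)
  expect_equal(st$B_hat %*% t(st$A_hat), X, tolerance = 1e-8)
  expect_lt(st$sigma_E2, 1e-10)
  ## zero matrix: zero scores, floor-level relevances
  st0 <- vbpca_init(matrix(0, 5, 4), Q = 2)
  expect_equal(st0$B_hat, matrix(0, 5, 2))
  expect_true(all(st0$C_B > 0))
  expect_error(vbpca_init(matrix(0, 5, 4), Q = 5), "min")
})

test_that("free energy decreases after one update in nearly every draw", {
  drops <- vapply(1:100, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 10), 30, 10)
    st <- vbpca_init(X, Q = 3)
    f0 <- free_energy(st, X)
    f1 <- free_energy(vbpca_update(st, X), X)
    is.finite(f0) && is.finite(f1) && f1 < f0
  }, logical(1))
  expect_gte(sum(drops), 95)
})

test_that("the C_B update identity holds exactly after each cycle", {
  X <- planted_rank1(seed = 5)
  st <- vbpca_init(X, Q = 5)
  for (k in 1:3) {
    st <- vbpca_update(st, X)
    dSB <- t(apply(st$Sigma_B, 3, diag))
    expect_equal(st$C_B - st$B_hat^2, dSB, tolerance = 1e-14)
    expect_equal(sum(st$C_A), 1, tolerance = 1e-12)
  }
})

test_that("covariance updates preserve symmetry and positive-definiteness", {
  X <- planted_rank1(N = 40, M = 12, seed = 7)
  st <- vbpca_init(X, Q = 4)
  for (k in 1:5) {
    st <- vbpca_update(st, X)
    expect_equal(st$Sigma_A, t(st$Sigma_A), tolerance = 1e-10)
    expect_gt(min(eigen(st$Sigma_A, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    for (i in c(1, 20, 40)) {
      S <- st$Sigma_B[, , i]
      expect_equal(S, t(S), tolerance = 1e-10)
      expect_gt(min(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
})

test_that("the noise-variance update is a nonnegative expected residual", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(48), 8, 6)
    st <- vbpca_update(vbpca_init(X, Q = 3), X)
    ## direct evaluation of the three-term expression
    G <- crossprod(st$A_hat) + 6 * st$Sigma_A
    sSB <- apply(st$Sigma_B, c(1, 2), sum)
    direct <- (sum(X^2) -
                 2 * sum(diag(t(X) %*% st$B_hat %*% t(st$A_hat))) +
                 sum(diag(G %*% (crossprod(st$B_hat) + sSB)))) / 48
    expect_gte(direct, 0)
    expect_equal(st$sigma_E2, max(direct, 1e-12), tolerance = 1e-10)
  }
})

test_that("free energy matches an independent term-by-term transcription", {
  X <- planted_rank1(N = 30, M = 10, seed = 3)
  st <- vbpca_init(X, Q = 4)
  for (k in 1:3) st <- vbpca_update(st, X)
  expect_equal(free_energy(st, X), oracle_free_energy(st, X),
               tolerance = 1e-10)
})

test_that("doubling sigma_E2 shifts F by the closed-form amount", {
  X <- planted_rank1(N = 20, M = 8, seed = 9)
  st <- vbpca_update(vbpca_init(X, Q = 3), X)
  f1 <- free_energy(st, X)
  st2 <- st; st2$sigma_E2 <- 2 * st$sigma_E2
  f2 <- free_energy(st2, X)
  s2 <- st$sigma_E2
  v2 <- sum(X^2)
  ## first two terms plus the sigma^-2 part of the trace halve/shift
  G <- crossprod(st$A_hat) + 8 * st$Sigma_A
  sSB <- apply(st$Sigma_B, c(1, 2), sum)
  cross <- -2 * sum((X %*% st$A_hat) * st$B_hat) +
    sum(G * (crossprod(st$B_hat) + sSB))
  expected <- (v2 / (2 * 2 * s2) - v2 / (2 * s2)) +
    (20 * 8 / 2) * log(2) +
    0.5 * cross * (1 / (2 * s2) - 1 / s2)
  expect_equal(f2 - f1, expected, tolerance = 1e-8)
})

test_that("a converged fit has a stable extraction under further updates", {
  X <- planted_rank1(N = 50, n_sig = 5, M = 16, seed = 4)
  fit <- vbpca_fit(X, Q = 4, n_top = 5, max_iter = 600, patience = 100)
  expect_true(attr(fit, "converged"))
  st2 <- vbpca_update(fit, X)
  sel1 <- order(fit$C_B[, 1], decreasing = TRUE)[1:5]
  sel2 <- order(st2$C_B[, 1], decreasing = TRUE)[1:5]
  expect_setequal(sel1, sel2)
  ## the relevances driving the extraction barely move
  rel <- abs(st2$C_B[sel1, 1] - fit$C_B[sel1, 1]) / fit$C_B[sel1, 1]
  expect_lt(max(rel), 1e-3)
})

test_that("the planted feature set is recovered in the high-signal regime", {
  X <- planted_rank1(N = 100, n_sig = 10, M = 20, amp = 3, seed = 6)
  fit <- vbpca_fit(X, Q = 5, n_top = 10)
  sel <- selected_features(vbpcafe_select(fit, q = 1, n_top = 10))
  expect_setequal(sel, 1:10)
  ## the reported state is the minimum-F state visited
  expect_equal(fit$F, min(attr(fit, "F_trace")))
})

test_that("fit rejects invalid iteration budgets", {
  X <- planted_rank1(N = 10, M = 6, seed = 2)
  expect_error(vbpca_fit(X, Q = 2, max_iter = 0), "max_iter")
  expect_error(vbpca_fit(X, Q = 2, max_iter = 50, patience = 100),
               "max_iter must be >= patience")
})

test_that("selection is ordered by C_B and bounded by N", {
  X <- planted_rank1(N = 20, M = 8, seed = 13)
  fit <- vbpca_fit(X, Q = 3, n_top = 5, max_iter = 150, patience = 50)
  all_feats <- vbpcafe_select(fit, q = 1, n_top = 20)
  expect_equal(tidy(all_feats)$score, sort(fit$C_B[, 1], decreasing = TRUE))
  expect_error(vbpcafe_select(fit, q = 1, n_top = 21), "n_top")
  expect_error(vbpcafe_select(fit, q = 4, n_top = 5), "q must be")
})

test_that("scaling the data scales B linearly and C_B quadratically", {
  X <- planted_rank1(N = 60, n_sig = 6, M = 16, amp = 2.5, seed = 10)
  f1 <- vbpca_fit(X, Q = 4, n_top = 6, max_iter = 500)
  f2 <- vbpca_fit(3 * X, Q = 4, n_top = 6, max_iter = 500)
  sig <- 1:6 # compare on the strong features, where relevances are stable
  expect_equal(abs(f2$B_hat[sig, 1]) / abs(f1$B_hat[sig, 1]),
               rep(3, 6), tolerance = 0.05)
  expect_equal(f2$C_B[sig, 1] / f1$C_B[sig, 1], rep(9, 6),
               tolerance = 0.05)
})
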