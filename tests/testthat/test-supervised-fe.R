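make_blocks <- function(means, n_per = 5, sd = 0.5, seed = 1, extra = NULL) {
  ## one row per element of `extra` list plus a first row with class means
  set.seed(seed)
  K <- length(means)
  labs <- rep(seq_len(K), each = n_per)
  x1 <- unlist(lapply(means, function(m) rnorm(n_per, m, sd)))
  X <- rbind(x1, if (!is.null(extra)) do.call(rbind, extra))
  rownames(X) <- NULL
  list(X = X, labels = factor(labs))
}

test_that("one-vs-one t-test FE matches scalar t.test oracles per pair", {
  d <- make_blocks(c(0, 10, 20, 30), seed = 4,
                   extra = list(rnorm(20, 0, 1)))
  res <- ttest_ovo_fe(d$X, d$labels, adjust_scope = "per_pair")
  ## oracle: feature 1, every pair significant via stats::t.test
  for (kk in list(c(1, 2), c(1, 3), c(3, 4))) {
    p_oracle <- t.test(d$X[1, d$labels == kk[1]],
                       d$X[1, d$labels == kk[2]])$p.value
    expect_lt(p_oracle, 0.05 / 6) # far below any BH threshold
  }
  expect_true(1 %in% selected_features(res))
  expect_false(2 %in% selected_features(res))
})

test_that("identical class blocks yield an empty t-test selection", {
  block <- matrix(rnorm(50), 10, 5)
  X <- cbind(block, block, block, block)
  res <- ttest_ovo_fe(X, rep(1:4, each = 5))
  expect_length(selected_features(res), 0)
})

test_that("t-test selection is monotone in alpha", {
  d <- random_labeled_matrix(30, 20, 4, seed = 12)
  d$X[1:5, ] <- d$X[1:5, ] + 2 * outer(rep(1, 5), as.integer(d$labels))
  s1 <- selected_features(ttest_ovo_fe(d$X, d$labels, alpha = 0.01))
  s2 <- selected_features(ttest_ovo_fe(d$X, d$labels, alpha = 0.10))
  expect_true(all(s1 %in% s2))
})

test_that("t-test FE errors when a class has fewer than 2 samples", {
  expect_error(ttest_ovo_fe(matrix(rnorm(10), 2, 5), c(1, 1, 2, 2, 3)),
               "at least 2 samples")
})

test_that("categorical regression P equals the lm/ANOVA F-test P", {
  d <- random_labeled_matrix(20, 20, 4, seed = 33)
  res <- categorical_regression_fe(d$X, d$labels, mode = "ranked",
                                   n_top = 5)
  tab <- tidy(res)
  for (i in seq_len(20)) {
    fit <- lm(d$X[i, ] ~ d$labels)
    p_oracle <- anova(fit)[["Pr(>F)"]][1]
    expect_equal(tab$p_value[tab$feature == i], p_oracle,
                 tolerance = 1e-10)
  }
})

test_that("ranked selection returns exactly n_top regardless of P", {
  d <- random_labeled_matrix(50, 20, 4, seed = 2)
  res <- categorical_regression_fe(d$X, d$labels, mode = "ranked",
                                   n_top = 10)
  expect_length(selected_features(res), 10)
  ## pure-noise P-values are not significant, yet 10 are still returned
  expect_gt(min(tidy(res)$adj_p), 0.05)
})

test_that("constant features get P = 1 and never outrank real signal", {
  d <- make_blocks(c(0, 1, 2, 3), seed = 6,
                   extra = list(rep(2, 20), rnorm(20)))
  res <- categorical_regression_fe(d$X, d$labels, mode = "ranked",
                                   n_top = 2)
  tab <- tidy(res)
  expect_equal(tab$p_value[tab$feature == 2], 1)
  expect_false(2 %in% selected_features(res))
})

test_that("categorical regression P is invariant to per-feature affine maps", {
  d <- random_labeled_matrix(10, 20, 4, seed = 8)
  p1 <- tidy(categorical_regression_fe(d$X, d$labels, mode = "ranked",
                                       n_top = 5))
  Xa <- d$X * 3.7 - 2
  p2 <- tidy(categorical_regression_fe(Xa, d$labels, mode = "ranked",
                                       n_top = 5))
  expect_equal(p1$p_value, p2$p_value, tolerance = 1e-9)
})

test_that("HSIC equals the three-term mean-form oracle and is nonnegative", {
  for (seed in 1:25) {
    d <- random_labeled_matrix(5, 6, 3, seed = seed)
    h <- hsic(d$X, d$labels)
    expect_equal(h, oracle_hsic_three_term(d$X, d$labels),
                 tolerance = 1e-10)
    expect_gte(h, -1e-10)
  }
  expect_equal(hsic(matrix(0, 4, 6), rep(1:2, 3)), 0)
})

test_that("HSIC is invariant under joint sample reordering", {
  d <- random_labeled_matrix(6, 12, 3, seed = 5)
  perm <- sample(12)
  expect_equal(hsic(d$X, d$labels),
               hsic(d$X[, perm], d$labels[perm]), tolerance = 1e-12)
})

test_that("a label-tracking feature beats all label permutations", {
  set.seed(9)
  labels <- rep(1:3, each = 4)
  x <- as.numeric(labels) + rnorm(12, 0, 0.01)
  h0 <- hsic(x, labels)
  hperm <- replicate(1000, hsic(x, sample(labels)))
  ## some permutations reproduce the same partition (the delta kernel is
  ## invariant to class renaming), so ties are allowed
  expect_gte(h0, max(hperm))
  expect_gt(mean(h0 > hperm), 0.95)
})

test_that("BAHSIC drop-1 ranking equals the additive per-feature ranking", {
  for (seed in 1:5) {
    d <- random_labeled_matrix(10, 12, 3, seed = 100 + seed)
    res <- bahsic_select(d$X, d$labels, n_target = 4)
    ## additivity: full HSIC is the sum of per-feature contributions
    expect_equal(hsic(d$X, d$labels),
                 sum(per_feature_hsic(d$X, d$labels)), tolerance = 1e-10)
    ## so survivors are just the top per-feature HSIC features
    top <- order(per_feature_hsic(d$X, d$labels), decreasing = TRUE)[1:4]
    expect_setequal(selected_features(res), top)
    ## and one-shot elimination agrees with stepwise
    res_batch <- bahsic_select(d$X, d$labels, n_target = 4,
                               drop_fraction = 1)
    expect_setequal(selected_features(res_batch), selected_features(res))
  }
})

test_that("BAHSIC handles edge cases", {
  d <- random_labeled_matrix(8, 12, 3, seed = 77)
  expect_setequal(selected_features(bahsic_select(d$X, d$labels,
                                                  n_target = 8)), 1:8)
  expect_error(bahsic_select(d$X, d$labels, n_target = 0), "positive")
  expect_error(hsic(d$X, rep(1, 5)), "mismatch")
})
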