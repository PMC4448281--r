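small_design <- function() {
  tibble::tibble(
    sample_id = c(paste0("T_r", 1:3), paste0("C_r", 1:3)),
    condition = rep(c("T2-1d", "C2-1d"), each = 3),
    role = rep(c("treatment", "control"), each = 3),
    pair_id = "2-1d",
    replicate = rep(1:3, 2))
}

test_that("condition designs are validated and unpaired conditions flagged", {
  d <- small_design()
  expect_s3_class(condition_design(d), "tbl_df")
  d_bad <- d[d$role == "treatment", ]
  expect_error(condition_design(d_bad), "lacks one of its members")
  d2 <- d
  d2$pair_id[d2$role == "treatment"] <- NA
  d2$pair_id[d2$role == "control"] <- NA
  expect_equal(attr(condition_design(d2), "unpaired"), "T2-1d")
})

test_that("group P-values are one-sided, oriented, and complementary", {
  set.seed(1)
  d <- small_design()
  X <- matrix(rnorm(60, 5), 10, 6, dimnames = list(paste0("g", 1:10),
                                                   d$sample_id))
  X[1, 1:3] <- X[1, 1:3] + 4 # planted treatment upregulation
  pg <- per_feature_group_pvalues(X, d, "2-1d", alternative = "greater")
  pl <- per_feature_group_pvalues(X, d, "2-1d", alternative = "less")
  expect_equal(pg$p_value + pl$p_value, rep(1, 10), tolerance = 1e-12)
  expect_lt(pg$p_value[1], 0.5)
  ## identical replicate values in both groups: exactly at the null middle
  X2 <- X; X2[, 4:6] <- X2[, 1:3]
  expect_equal(per_feature_group_pvalues(X2, d, "2-1d")$p_value,
               rep(0.5, 10))
  expect_error(per_feature_group_pvalues(X, d, "nope"), "no treatment")
})

test_that("selected-vs-others tests detect a planted log-P shift", {
  set.seed(2)
  log_p <- rnorm(100, -1)
  sel <- 1:20
  r0 <- selected_vs_others_test(log_p, sel)
  expect_equal(r0$P_gt + r0$P_lt, 1, tolerance = 1e-12)
  shifted <- log_p; shifted[sel] <- shifted[sel] - 10
  expect_lt(selected_vs_others_test(shifted, sel)$P_lt, 1e-6)
  expect_error(selected_vs_others_test(log_p, integer(0)), "nonempty")
})

test_that("null selected-vs-others P-values are roughly uniform", {
  set.seed(3)
  p <- replicate(40, {
    lp <- rnorm(60)
    selected_vs_others_test(lp, sample(60, 15))$P_lt
  })
  expect_gt(mean(p), 0.3); expect_lt(mean(p), 0.7)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("log-ratio group tests respond to planted fold changes", {
  set.seed(4)
  d <- small_design()
  X <- matrix(rexp(300, 1 / 5) + 1, 50, 6,
              dimnames = list(paste0("g", 1:50), d$sample_id))
  sel <- 1:10
  X[sel, 1:3] <- X[sel, 1:3] * 2 # two-fold up under treatment
  r <- log_ratio_group_test(X, d, "2-1d", sel)
  expect_lt(r$P_control_lt, 0.01)
  ## swapping the roles swaps the two P-values
  d_sw <- d; d_sw$role <- rev(d$role)
  r_sw <- log_ratio_group_test(X, d_sw, "2-1d", sel)
  expect_equal(r$P_control_lt, r_sw$P_control_gt, tolerance = 1e-12)
  ## identical treated/control: flat ratios, both sides at 0.5
  X2 <- X; X2[, 1:3] <- X2[, 4:6]
  r2 <- log_ratio_group_test(X2, d, "2-1d", sel)
  expect_equal(r2$P_control_lt, 0.5)
  expect_equal(r2$P_control_gt, 0.5)
  ## nonpositive expression is rejected
  X3 <- X; X3[1, 1] <- 0
  expect_error(log_ratio_group_test(X3, d, "2-1d", sel), "nonpositive")
})

test_that("correlation significance matches the t transform", {
  ## the worked example: r = -0.37 over 48 samples is significant at ~1%
  res <- correlation_significance(-0.37, 48)
  expect_lt(abs(res$p_value - 0.01), 0.005)
  ## r = 0: no evidence at all
  expect_equal(correlation_significance(0, 48)$p_value, 1)
  ## independent CDF evaluation at r = 0.5
  r <- 0.5
  t_expected <- r * sqrt(46) / sqrt(1 - r^2)
  res <- correlation_significance(r, 48)
  expect_equal(res$t_stat, t_expected, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * (1 - pt(t_expected, 46)),
               tolerance = 1e-12)
  ## antisymmetric t, symmetric two-sided P
  expect_equal(correlation_significance(-r, 48)$t_stat, -t_expected)
  expect_equal(correlation_significance(-r, 48)$p_value, res$p_value)
  expect_warning(correlation_significance(1, 10), "limiting")
  expect_error(correlation_significance(0.5, 2), "M must be")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12)) # monotone step-up
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("7mer-m8 matching agrees with a sliding-window oracle", {
  ## constructed site at a known offset
  mir <- "UGGAAUGUAAAGAAGUAUGUAU"
  site <- "ACATTCC" # reverse complement of positions 2-8 (GGAAUGU)
  utr <- paste0("GGGGG", site, "GGGG")
  hits <- seed_match_7mer_m8(mir, utr)
  expect_equal(hits$utr_offset, 5L)
  expect_equal(hits$matched_site, site)
  ## no match when the complement cannot occur
  expect_equal(nrow(seed_match_7mer_m8("UCCCCCCCCC",
                                       strrep("A", 50))), 0)
  ## U/T interchangeable in the miRNA
  expect_equal(seed_match_7mer_m8(chartr("U", "T", mir), utr)$utr_offset,
               5L)
  ## ambiguous bases never match
  utr_n <- paste0("GGGGG", sub("A", "N", site), "GGGG")
  expect_equal(nrow(seed_match_7mer_m8(mir, utr_n)), 0)
  ## random UTRs against the brute-force scan
  set.seed(6)
  for (k in 1:10) {
    m <- paste0(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    u <- paste0(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    expect_equal(seed_match_7mer_m8(m, u)$utr_offset,
                 oracle_seed_scan(m, u))
  }
})

test_that("pair integration flags planted pairs as significant negatives", {
  fx <- generate_fixture(fixture_spec(effect_size = 0.8, noise_sd = 0.3,
                                      seed = 23))
  pairs <- integrate_pairs(fx$mirna, fx$mrna,
                           selected_mirna = unique(fx$probe_map$mirna_id)[1:10],
                           selected_mrna = rownames(fx$mrna)[1:15],
                           mirna_seqs = fx$mirna_seqs,
                           utr_seqs = fx$utr_seqs,
                           probe_map = fx$probe_map)
  planted <- dplyr::inner_join(pairs, fx$planted_pairs,
                               by = c("mirna_id", "mrna_id"))
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$r < 0))
  expect_true(all(planted$significant))
  expect_true(all(planted$seed_match))
})

test_that("loading correlations recover the planted anti-correlation", {
  fx <- generate_fixture(fixture_spec(n_mrna = 25, n_planted_pairs = 10,
                                      effect_size = 0.9, noise_sd = 0.2,
                                      seed = 29))
  ea <- pca_embed(fx$mirna)
  eb <- pca_embed(fx$mrna, standardize_features = TRUE)
  self <- suppressWarnings(loading_correlation(ea, ea)) # |r| = 1 edge case
  expect_equal(self$r, 1, tolerance = 1e-12)
  res <- loading_correlation(ea, eb)
  expect_lt(res$r, 0)
  ## condition-averaged variant runs over 12 points
  resc <- loading_correlation(ea, eb, by_condition = TRUE,
                              design = fx$design)
  expect_equal(resc$n, 12)
})

test_that("cv stability counts selections over replicate subsamplings", {
  fx <- generate_fixture(fixture_spec(n_mirna = 5, n_mrna = 30,
                                      n_planted_pairs = 3,
                                      effect_size = 0.9, noise_sd = 0.15,
                                      seed = 19))
  ## a method with a fixed answer: frequencies are 0 or n_samplings
  fixed <- cv_stability(fx$mrna, fx$design, function(X) 1:3,
                        n_samplings = 10, seed = 1)
  expect_setequal(unique(fixed$frequency), c(0, 10))
  expect_equal(attr(fixed, "n_ok"), 10)
  ## CPCAFE on a strong planted signal: bimodal frequencies
  cp <- function(X) selected_features(cpcafe_select(
    pca_embed(X, standardize_features = TRUE), n_top = 3))
  st <- cv_stability(fx$mrna, fx$design, cp, n_samplings = 25, seed = 2)
  expect_gte(mean(st$frequency <= 2 | st$frequency >= 23), 0.9)
  ## failures are recorded, not fatal
  flaky <- local({
    calls <- 0
    function(X) {
      calls <<- calls + 1
      if (calls %% 2 == 0) stop("boom") else 1:2
    }
  })
  fl <- cv_stability(fx$mrna, fx$design, flaky, n_samplings = 6, seed = 3)
  expect_equal(attr(fl, "n_failed"), 3)
  expect_equal(max(fl$frequency), 3)
})
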