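#' Condition design table
#'
#' Validates the per-sample design of a paired treatment/control study:
#' columns `sample_id`, `condition`, `role` (`"treatment"`/`"control"`),
#' `pair_id` (shared by a treatment condition and its matched control;
#' `NA` for unpaired treatment conditions, which are excluded from paired
#' computations) and `replicate`.
#'
#' @param design Data frame with the columns above.
#' @return The validated design as a tibble, with attribute
#'   `unpaired` listing flagged unpaired treatment conditions.
#' @export
condition_design <- function(design) {
  need <- c("sample_id", "condition", "role", "pair_id", "replicate")
  if (!all(need %in% names(design)))
    abort(paste0("design must have columns: ", paste(need, collapse = ", ")))
  if (!all(design$role %in% c("treatment", "control")))
    abort("role must be 'treatment' or 'control'.")
  paired <- design[!is.na(design$pair_id), ]
  for (pid in unique(paired$pair_id)) {
    roles <- unique(paired$role[paired$pair_id == pid])
    if (length(roles) != 2)
      abort(sprintf("pair '%s' lacks one of its members.", pid))
  }
  out <- as_tibble(design)
  attr(out, "unpaired") <-
    unique(design$condition[design$role == "treatment" &
                              is.na(design$pair_id)])
  out
}

## sample ids of one role within a condition pair
pair_samples <- function(design, pair, role) {
  s <- design$sample_id[!is.na(design$pair_id) & design$pair_id == pair &
                          design$role == role]
  if (length(s) == 0)
    abort(sprintf("no %s samples for condition pair '%s'.", role, pair))
  s
}

#' Per-feature treatment-vs-control P-values for one condition pair
#'
#' One Welch t test per feature between the treatment and control
#' replicates of a paired condition. One-sided by default and oriented so
#' that `P < 0.5` indicates treatment upregulation under
#' `alternative = "greater"`; the two one-sided P-values of a feature sum
#' to 1.
#'
#' @param x An [expression_matrix()] or matrix with sample columns named as
#'   in `design`.
#' @param design A [condition_design()].
#' @param condition_pair A `pair_id` present in the design.
#' @param alternative `"greater"` (treatment > control), `"less"`, or
#'   `"two_sided"`.
#' @return Tibble: `feature_id`, `p_value`.
#' @export
per_feature_group_pvalues <- function(x, design, condition_pair,
                                      alternative = c("greater", "less",
                                                      "two_sided")) {
  alternative <- match.arg(alternative)
  X <- as_values(x)
  jt <- match(pair_samples(design, condition_pair, "treatment"), colnames(X))
  jc <- match(pair_samples(design, condition_pair, "control"), colnames(X))
  if (anyNA(jt) || anyNA(jc)) abort("design samples missing from matrix.")
  if (length(jt) < 2 || length(jc) < 2)
    abort("both conditions need >= 2 replicates.")
  w <- welch_t_rows(X[, jt, drop = FALSE], X[, jc, drop = FALSE])
  p <- switch(alternative,
              greater = pt(w$t, w$df, lower.tail = FALSE),
              less = pt(w$t, w$df, lower.tail = TRUE),
              two_sided = w$p_two)
  tibble(feature_id = rownames(X) %||% as.character(seq_len(nrow(X))),
         p_value = unname(p))
}

#' Compare log P-values of selected features against the rest
#'
#' Two one-sided two-sample Welch t tests on (natural) logarithmic
#' P-values, selected features vs all others. A small `P_lt` means the
#' selected features' log P-values are systematically *lower* (more
#' significant) than the rest.
#'
#' @param log_p Per-feature logarithmic P-values.
#' @param selected Indices of the selected features.
#' @return List with `P_gt` and `P_lt` (they sum to 1).
#' @export
selected_vs_others_test <- function(log_p, selected) {
  others <- setdiff(seq_along(log_p), selected)
  if (length(selected) == 0 || length(others) == 0)
    abort("both groups must be nonempty.")
  a <- log_p[selected]; b <- log_p[others]
  list(P_gt = t.test(a, b, alternative = "greater")$p.value,
       P_lt = t.test(a, b, alternative = "less")$p.value)
}

#' Group test on treated/control log expression ratios
#'
#' Per feature, expression is replicate-averaged within the treated and
#' control condition of the pair, the log ratio
#' `log(treated_avg / control_avg)` taken, and the selected features'
#' ratios compared to the remaining features' with one-sided t tests in
#' both directions.
#'
#' @inheritParams per_feature_group_pvalues
#' @param selected Indices of selected features (nonempty).
#' @return List: `P_control_lt` (selected ratios greater — expression
#'   higher under treatment), `P_control_gt`, and `log_ratio` (per-feature
#'   values).
#' @export
log_ratio_group_test <- function(x, design, condition_pair, selected) {
  X <- as_values(x)
  if (any(X <= 0))
    abort("nonpositive expression values: log ratios undefined; offset the matrix first.")
  if (length(selected) == 0) abort("selected must be nonempty.")
  jt <- match(pair_samples(design, condition_pair, "treatment"), colnames(X))
  jc <- match(pair_samples(design, condition_pair, "control"), colnames(X))
  lr <- log(rowMeans(X[, jt, drop = FALSE]) /
              rowMeans(X[, jc, drop = FALSE]))
  others <- setdiff(seq_len(nrow(X)), selected)
  ## degenerate case: identical treated and control expression gives flat
  ## ratios in both groups — no evidence either way
  one_sided <- function(a, b, alternative) {
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) return(0.5)
    t.test(a, b, alternative = alternative)$p.value
  }
  list(P_control_lt = one_sided(lr[selected], lr[others], "greater"),
       P_control_gt = one_sided(lr[selected], lr[others], "less"),
       log_ratio = lr)
}

#' Correlate PC1 sample loadings of two embeddings
#'
#' Pearson correlation between the first-PC sample loadings of two
#' embeddings over the shared samples (or over condition-averaged loadings
#' with `by_condition = TRUE`); the significance comes from the t
#' transform of [correlation_significance()] with `M` = number of points.
#' Used to compare the dominant expression programs of two omics layers
#' measured on the same samples.
#'
#' The raw sign of a PC is a convention, so before correlating, each
#' layer's PC1 loading is oriented against that layer's own per-sample
#' mean expression (`orient = "expression"`, the default): the loading is
#' flipped so that it correlates positively with overall expression of its
#' layer. The sign of the reported `r` then says whether high expression
#' of one layer accompanies high (`r > 0`) or low (`r < 0`) expression of
#' the other — the reading used when contrasting miRNA induction against
#' mRNA suppression. `orient = "none"` keeps the embeddings' stored signs.
#'
#' @param emb_a,emb_b [pca_embed()] results over the same samples.
#' @param by_condition Average loadings within conditions first?
#' @param design Required when `by_condition`; a [condition_design()].
#' @param orient PC1 sign handling; see Details.
#' @return Tibble row: `r`, `t_stat`, `p_value`, `n`.
#' @export
loading_correlation <- function(emb_a, emb_b, by_condition = FALSE,
                                design = NULL,
                                orient = c("expression", "none")) {
  orient <- match.arg(orient)
  if (!identical(emb_a$sample_ids, emb_b$sample_ids))
    abort("embeddings must share the same samples.")
  orient1 <- function(emb) {
    a <- emb$sample_loadings[, 1]
    if (orient == "expression" && !is.null(emb$sample_means)) {
      al <- cor(a, emb$sample_means)
      if (!is.na(al) && al < 0) a <- -a
    }
    a
  }
  a <- orient1(emb_a)
  b <- orient1(emb_b)
  if (by_condition) {
    if (is.null(design)) abort("design required when by_condition = TRUE.")
    cond <- design$condition[match(emb_a$sample_ids, design$sample_id)]
    a <- tapply(a, cond, mean)
    b <- tapply(b, cond, mean)
  }
  res <- correlation_significance(cor(a, b), length(a))
  res$n <- length(a)
  res
}

#' Significance of Pearson correlation coefficients
#'
#' Transforms each correlation to \eqn{t = r\sqrt{M-2}/\sqrt{1-r^2}},
#' which follows the t distribution with `M - 2` degrees of freedom under
#' the null; two-sided P-values are BH-adjusted over the supplied batch
#' and flagged significant below `alpha`. `|r| = 1` is the limiting case
#' `P = 0` (flagged with a warning).
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param M Number of samples the correlations were computed over
#'   (`>= 3`).
#' @param alpha Significance level on adjusted P-values.
#' @return Tibble: `r`, `t_stat`, `p_value`, `adjusted_p`, `significant`.
#' @examples
#' correlation_significance(-0.37, 48) # P ~ 0.01
#' @export
correlation_significance <- function(r, M, alpha = 0.05) {
  if (M < 3) abort("M must be >= 3.")
  if (any(abs(r) > 1)) abort("|r| must be <= 1.")
  if (any(abs(r) == 1))
    warning("|r| = 1: limiting case, P set to 0.")
  t_stat <- r * sqrt(M - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(abs(r) == 1, 0, 2 * pt(abs(t_stat), M - 2, lower.tail = FALSE))
  adj <- bh_adjust(p)
  tibble(r = r, t_stat = t_stat, p_value = p, adjusted_p = adj,
         significant = adj < alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated front end to `stats::p.adjust(method = "BH")`:
#' monotone step-up adjusted P-values, capped at 1.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

## DNA 7-mer a 7mer-m8 site must equal: reverse complement of miRNA
## positions 2-8 (1-based, 5'->3')
seed_site_7mer_m8 <- function(mirna_seq) {
  if (nchar(mirna_seq) < 8) abort("miRNA must be at least 8 nt long.")
  seed <- chartr("Uu", "Tt", substr(mirna_seq, 2, 8))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed)))
}

#' 7mer-m8 seed matching
#'
#' Scans a 3'UTR (5'->3') for exact 7-nt matches to the reverse complement
#' of miRNA positions 2-8 (seed plus position 8) — the canonical 7mer-m8
#' target site. Ambiguous bases (`N`) never match. `U` and `T` in the
#' miRNA are interchangeable.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3' (RNA or DNA alphabet),
#'   length `>= 8`.
#' @param utr_seq UTR/transcript sequence, 5'->3' (DNA alphabet).
#' @param mirna_id,mrna_id Optional identifiers carried into the output.
#' @return Tibble of matches: `mirna_id`, `mrna_id`, `utr_offset`
#'   (0-based), `matched_site` (the 7-nt site).
#' @examples
#' seed_match_7mer_m8("UGGAAUGUAAAGAAGUAUGUAU",
#'                    paste0("AAAA", "ACATTCC", "GGGG"))
#' @export
seed_match_7mer_m8 <- function(mirna_seq, utr_seq, mirna_id = NA_character_,
                               mrna_id = NA_character_) {
  site <- seed_site_7mer_m8(as.character(mirna_seq))
  hits <- Biostrings::matchPattern(site,
                                   Biostrings::DNAString(as.character(utr_seq)),
                                   fixed = TRUE)
  starts <- Biostrings::start(hits)
  tibble(mirna_id = rep(mirna_id, length(starts)),
         mrna_id = rep(mrna_id, length(starts)),
         utr_offset = starts - 1L,
         matched_site = rep(site, length(starts)))
}

#' miRNA-mRNA pair table: seed match, correlation, significance
#'
#' The downstream integration step: for every (selected miRNA, selected
#' mRNA) pair, Pearson correlation of expression across the shared
#' samples, t-based significance with BH adjustment over the batch, and a
#' 7mer-m8 seed-match flag from the supplied sequences. With multiple
#' probes per miRNA, per-probe correlations are summarized by their
#' median.
#'
#' @param mirna,mrna Probe-level and gene-level [expression_matrix()]
#'   objects over the same samples.
#' @param selected_mirna Character vector of miRNA IDs to test.
#' @param selected_mrna Character vector of mRNA IDs to test.
#' @param mirna_seqs Named `RNAStringSet`/character of mature miRNA
#'   sequences.
#' @param utr_seqs Named `DNAStringSet`/character of UTR sequences.
#' @param probe_map Optional tibble (`probe_id`, `mirna_id`) mapping
#'   miRNA probes; defaults to identity (row names are miRNA IDs).
#' @param alpha Significance level on adjusted P-values.
#' @return Tibble: `mirna_id`, `mrna_id`, `seed_match`, `n_probes`, `r`,
#'   `t_stat`, `p_value`, `adjusted_p`, `significant`.
#' @export
integrate_pairs <- function(mirna, mrna, selected_mirna, selected_mrna,
                            mirna_seqs = NULL, utr_seqs = NULL,
                            probe_map = NULL, alpha = 0.05) {
  Xmi <- as_values(mirna); Xm <- as_values(mrna)
  if (!identical(colnames(Xmi), colnames(Xm)))
    abort("miRNA and mRNA matrices must share the same samples.")
  if (is.null(probe_map))
    probe_map <- tibble(probe_id = rownames(Xmi), mirna_id = rownames(Xmi))
  M <- ncol(Xmi)
  grid <- expand.grid(mirna_id = selected_mirna, mrna_id = selected_mrna,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mi <- grid$mirna_id[i]; mr <- grid$mrna_id[i]
    probes <- probe_map$probe_id[probe_map$mirna_id == mi]
    probes <- intersect(probes, rownames(Xmi))
    if (length(probes) == 0 || !mr %in% rownames(Xm)) return(NULL)
    rr <- vapply(probes, function(p) cor(Xmi[p, ], Xm[mr, ]), numeric(1))
    sm <- NA
    if (!is.null(mirna_seqs) && !is.null(utr_seqs) &&
        mi %in% names(mirna_seqs) && mr %in% names(utr_seqs)) {
      sm <- nrow(seed_match_7mer_m8(as.character(mirna_seqs[[mi]]),
                                    as.character(utr_seqs[[mr]]))) > 0
    }
    tibble(mirna_id = mi, mrna_id = mr, seed_match = sm,
           n_probes = length(probes), r = stats::median(rr))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  sig <- correlation_significance(out$r, M, alpha = alpha)
  dplyr::bind_cols(out, sig[, c("t_stat", "p_value", "adjusted_p",
                                "significant")])
}

#' Selection stability under replicate cross-validation
#'
#' Repeatedly drops one replicate per condition uniformly at random,
#' reruns a feature-extraction method on the reduced data set, and counts
#' how often each feature is selected. Stable methods show a bimodal
#' frequency profile (features selected always or never).
#'
#' @param x An [expression_matrix()] with sample columns named as in
#'   `design`.
#' @param design A [condition_design()].
#' @param fe_method Function taking the subsampled matrix and returning
#'   selected feature indices (relative to the full feature set) or an
#'   [fe_result].
#' @param n_samplings Number of subsampling rounds (default 100).
#' @param seed Integer seed.
#' @return Tibble: `feature_id`, `frequency` (in `[0, n_ok]`), plus
#'   attributes `n_ok` (successful samplings) and `n_failed`.
#' @export
cv_stability <- function(x, design, fe_method, n_samplings = 100, seed = 1) {
  X <- as_values(x)
  set.seed(seed)
  freq <- numeric(nrow(X))
  n_ok <- 0L; n_failed <- 0L
  conds <- split(design$sample_id, design$condition)
  for (b in seq_len(n_samplings)) {
    keep <- unlist(lapply(conds, function(s) {
      if (length(s) < 2) s else setdiff(s, sample(s, 1))
    }), use.names = FALSE)
    Xs <- X[, match(intersect(colnames(X), keep), colnames(X)), drop = FALSE]
    sel <- tryCatch({
      res <- fe_method(Xs)
      if (inherits(res, "fe_result")) selected_features(res) else res
    }, error = function(e) NULL)
    if (is.null(sel)) { n_failed <- n_failed + 1L; next }
    n_ok <- n_ok + 1L
    freq[sel] <- freq[sel] + 1
  }
  out <- tibble(feature_id = rownames(X) %||%
                  as.character(seq_len(nrow(X))),
                frequency = freq)
  attr(out, "n_ok") <- n_ok
  attr(out, "n_failed") <- n_failed
  out
}
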