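#' Confusion counts of a feature selection against ground truth
#'
#' Standard set-overlap counts: TP features are selected and truly
#' distinct, TN neither, FP selected but null, FN distinct but missed.
#'
#' @param selected Integer vector of selected feature indices.
#' @param truth Integer vector of truly distinct feature indices.
#' @param N Total feature count.
#' @return A `confusion_counts` list (`TP`, `TN`, `FP`, `FN`).
#' @examples
#' confusion(1:5, 1:10, 100)
#' @export
confusion <- function(selected, truth, N) {
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  if (length(selected) && (min(selected) < 1 || max(selected) > N))
    abort("selected indices out of range 1..N.")
  if (length(truth) && (min(truth) < 1 || max(truth) > N))
    abort("truth indices out of range 1..N.")
  TP <- length(intersect(selected, truth))
  FP <- length(setdiff(selected, truth))
  FN <- length(setdiff(truth, selected))
  structure(list(TP = TP, TN = N - TP - FP - FN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' in `[-1, 1]`; defined as 0 when any denominator factor vanishes.
#'
#' @param x A [confusion()] result.
#' @return Scalar MCC.
#' @examples
#' mcc(confusion(1:10, 1:10, 100)) # 1
#' @export
mcc <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  with(x, {
    den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    if (den == 0) 0 else (TP * TN - FP * FN) / den
  })
}

#' F measure
#'
#' Harmonic mean of sensitivity and precision,
#' \eqn{F = 2TP / ((TP+FP) + (TP+FN))}; defined as 0 when the denominator
#' vanishes (nothing selected and nothing to find).
#'
#' @inheritParams mcc
#' @return Scalar F in `[0, 1]`.
#' @export
f_measure <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  with(x, {
    den <- 2 * TP + FP + FN
    if (den == 0) 0 else 2 * TP / den
  })
}

## method registry for the benchmark: each takes (X, labels, n_top) and
## returns selected feature indices
benchmark_methods <- function() {
  list(
    "ttest" = function(X, labels, n_top)
      selected_features(ttest_ovo_fe(X, labels)),
    "catreg-adj" = function(X, labels, n_top)
      selected_features(categorical_regression_fe(X, labels,
                                                  mode = "adjusted")),
    "catreg-rank" = function(X, labels, n_top)
      selected_features(categorical_regression_fe(X, labels,
                                                  mode = "ranked",
                                                  n_top = n_top)),
    "bahsic" = function(X, labels, n_top)
      selected_features(bahsic_select(X, labels, n_target = n_top)),
    "vbpcafe" = function(X, labels, n_top) {
      fit <- vbpca_fit(X, Q = 10, n_top = n_top)
      selected_features(vbpcafe_select(fit, q = 1, n_top = n_top))
    },
    "cpcafe" = function(X, labels, n_top) {
      emb <- pca_embed(X, center = "none")
      selected_features(cpcafe_select(emb, pc = 1, n_top = n_top))
    })
}

## derived per-ensemble seed; kept below 2^31
ensemble_seed <- function(seed, s_index, ensemble, salt = 0L) {
  as.integer((as.numeric(seed) + 1000003 * s_index + 7919 * salt +
                ensemble) %% 2147483647)
}

#' Run the simulation benchmark
#'
#' For every separation scale in `s_values` and every ensemble: simulate a
#' data set from `config`, optionally mislabel the label vector (labels
#' only — the data are untouched, and the unsupervised methods never see
#' labels), run each FE method, and score the selection against the known
#' distinct features with MCC and F. Per-ensemble scores and per-method
#' means with standard errors are returned.
#'
#' @param methods Character vector drawn from `"ttest"`, `"catreg-adj"`,
#'   `"catreg-rank"`, `"bahsic"`, `"vbpcafe"`, `"cpcafe"`.
#' @param config A [sim_config()].
#' @param s_values Separation scales to sweep.
#' @param mislabel Optional [mislabel_scheme()] applied to each ensemble's
#'   labels.
#' @param seed Root seed; per-ensemble seeds are derived deterministically
#'   so any ensemble is reproducible in isolation.
#' @param n_ensembles Ensembles per scale (default from `config`).
#' @param n_top Selection size for fixed-size methods.
#' @return An `fe_benchmark` list: `scores` (tibble: method, s, ensemble,
#'   mcc, f, n_selected), `summary` (tibble: method, s, mean_mcc, se_mcc,
#'   mean_f, se_f, n_ensembles), `config`, `seed`.
#' @examples
#' b <- run_benchmark("cpcafe", sim_config(n_ensembles = 5), s_values = 2,
#'                    seed = 1)
#' b$summary
#' @export
run_benchmark <- function(methods, config = sim_config(), s_values = c(2, 1, 0.5),
                          mislabel = NULL, seed = 1,
                          n_ensembles = config$n_ensembles, n_top = 10) {
  registry <- benchmark_methods()
  bad <- setdiff(methods, names(registry))
  if (length(bad)) abort(paste0("unknown method(s): ",
                                paste(bad, collapse = ", ")))
  rows <- vector("list", length(s_values) * n_ensembles * length(methods))
  r <- 0L
  for (si in seq_along(s_values)) {
    cfg <- config; cfg$s <- s_values[si]
    for (e in seq_len(n_ensembles)) {
      d <- simulate_dataset(cfg, seed = ensemble_seed(seed, si, e))
      labels <- sample_labels(d$data)
      if (!is.null(mislabel)) {
        set.seed(ensemble_seed(seed, si, e, salt = 1L))
        labels <- apply_mislabeling(labels, mislabel)$labels
      }
      X <- as_values(d$data)
      for (m in methods) {
        sel <- tryCatch(registry[[m]](X, labels, n_top), error = function(err)
          abort(sprintf("method %s failed on ensemble %d (s = %g): %s",
                        m, e, cfg$s, conditionMessage(err))))
        cc <- confusion(sel, d$truth, cfg$N)
        r <- r + 1L
        rows[[r]] <- tibble(method = m, s = cfg$s, ensemble = e,
                            mcc = mcc(cc), f = f_measure(cc),
                            n_selected = length(sel))
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  summary <- scores |>
    dplyr::group_by(.data$method, .data$s) |>
    dplyr::summarise(mean_mcc = mean(.data$mcc),
                     se_mcc = sd(.data$mcc) / sqrt(dplyr::n()),
                     mean_f = mean(.data$f),
                     se_f = sd(.data$f) / sqrt(dplyr::n()),
                     mean_n_selected = mean(.data$n_selected),
                     n_ensembles = dplyr::n(), .groups = "drop")
  structure(list(scores = scores, summary = summary, config = config,
                 seed = seed),
            class = "fe_benchmark")
}

#' @export
print.fe_benchmark <- function(x, ...) {
  cat(sprintf("fe_benchmark: %d method(s), s in {%s}, %d ensembles\n",
              length(unique(x$summary$method)),
              paste(sort(unique(x$summary$s)), collapse = ", "),
              max(x$summary$n_ensembles)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method
tidy.fe_benchmark <- function(x, ...) x$scores

#' @exportS3Method
glance.fe_benchmark <- function(x, ...) x$summary

#' Bar chart of benchmark performance
#'
#' Mean MCC and F per method and separation scale, with standard-error
#' bars — the standard summary view of the simulation benchmark.
#'
#' @param object An `fe_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.fe_benchmark <- function(object, ...) {
  su <- object$summary
  long <- dplyr::bind_rows(
    tibble(method = su$method, s = su$s, measure = "MCC",
           value = su$mean_mcc, se = su$se_mcc),
    tibble(method = su$method, s = su$s, measure = "F",
           value = su$mean_f, se = su$se_f))
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$value,
                                     fill = factor(.data$s))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = NULL, fill = "s") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
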