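#' Run a configured workflow
#'
#' Single programmatic entry point wiring the package's modules into the
#' two study workflows (simulation benchmark; miRNA-mRNA integration) plus
#' the individual steps, driven by a config list or a YAML file. Every run
#' writes its outputs under `out_dir` together with a `manifest.json`
#' recording the workflow, parameters, seed, package version and MD5
#' checksums of the outputs, so reruns are verifiable.
#'
#' Supported `workflow` values and their main outputs:
#' \describe{
#'   \item{`simulate`}{one simulated data set: `matrix.tsv`, `labels.tsv`.}
#'   \item{`fixture`}{the synthetic two-omics fixture via
#'     [write_fixture()].}
#'   \item{`fe`}{one FE method (`method` in `ttest`, `catreg-adj`,
#'     `catreg-rank`, `bahsic`) on a matrix + label map: `selected.tsv`.}
#'   \item{`cpcafe` / `vbpcafe`}{unsupervised FE on a matrix:
#'     `selected.tsv` (+ `embedding.tsv` / `cb.tsv`, `f_trace.tsv`).}
#'   \item{`benchmark`}{[run_benchmark()]: `summary.tsv`, `scores.tsv`.}
#'   \item{`integrate`}{[integrate_pairs()] on fixture-layout inputs:
#'     `pairs.tsv`.}
#' }
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return Invisibly, the manifest list.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  wf <- config[["workflow"]]
  if (is.null(wf)) abort("config must name a workflow.")
  out_dir <- config[["out_dir"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config[["seed"]] %||% 1L)
  for (f in config[["inputs"]] %||% list())
    if (!file.exists(f)) abort(sprintf("input file not found: %s", f))

  outputs <- switch(
    wf,
    simulate = {
      cfg <- sim_config(N = config[["n"]] %||% 100,
                        n_prime = config[["n_prime"]] %||% 10,
                        K = config[["k"]] %||% 4, M = config[["m"]] %||% 20,
                        s = config[["s"]] %||% 2)
      d <- simulate_dataset(cfg, seed = seed)
      write_expression(d$data, file.path(out_dir, "matrix.tsv"),
                       map_path = file.path(out_dir, "labels.tsv"))
      c("matrix.tsv", "labels.tsv")
    },
    fixture = {
      spec <- do.call(fixture_spec, c(config[["fixture"]] %||% list(),
                                      list(seed = seed)))
      write_fixture(generate_fixture(spec), out_dir)
      c("mirna.tsv", "mrna.tsv", "design.tsv", "planted_pairs.tsv",
        "probe_map.tsv", "mirna.fa", "utr.fa")
    },
    fe = {
      x <- read_expression(config[["matrix"]], map_path = config[["labels"]])
      res <- switch(config[["method"]],
                    "ttest" = ttest_ovo_fe(x, alpha = config[["alpha"]] %||% 0.05),
                    "catreg-adj" = categorical_regression_fe(
                      x, mode = "adjusted", alpha = config[["alpha"]] %||% 0.05),
                    "catreg-rank" = categorical_regression_fe(
                      x, mode = "ranked", n_top = config[["n_top"]] %||% 10),
                    "bahsic" = bahsic_select(
                      x, n_target = config[["n_top"]] %||% 10,
                      drop_fraction = config[["drop_fraction"]]),
                    abort(sprintf("unknown fe method '%s'.", config[["method"]])))
      write.table(tidy(res), file.path(out_dir, "selected.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      "selected.tsv"
    },
    cpcafe = {
      x <- read_expression(config[["matrix"]])
      emb <- pca_embed(x,
                       standardize_features =
                         isTRUE(config[["standardize"]]),
                       center = config[["center"]] %||% "sample")
      res <- cpcafe_select(emb, pc = config[["pc"]] %||% 1,
                           n_top = config[["n_top"]] %||% 10,
                           exclude_pc = config[["exclude_pc"]],
                           exclude_quantile =
                             config[["exclude_quantile"]] %||% 0.99)
      write.table(tidy(res), file.path(out_dir, "selected.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(tidy(emb), file.path(out_dir, "embedding.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      c("selected.tsv", "embedding.tsv")
    },
    vbpcafe = {
      x <- read_expression(config[["matrix"]])
      fit <- vbpca_fit(x, Q = config[["q"]] %||% 10,
                       n_top = config[["n_top"]] %||% 10,
                       max_iter = config[["max_iter"]] %||% 1000,
                       patience = config[["patience"]] %||% 100)
      res <- vbpcafe_select(fit, q = 1, n_top = config[["n_top"]] %||% 10,
                            feature_ids = rownames(x))
      write.table(tidy(res), file.path(out_dir, "selected.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(tidy(fit), file.path(out_dir, "cb.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(iteration = seq_along(attr(fit, "F_trace")),
                             F = attr(fit, "F_trace")),
                  file.path(out_dir, "f_trace.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      c("selected.tsv", "cb.tsv", "f_trace.tsv")
    },
    benchmark = {
      cfg <- sim_config(N = config[["n"]] %||% 100,
                        n_prime = config[["n_prime"]] %||% 10,
                        K = config[["k"]] %||% 4, M = config[["m"]] %||% 20,
                        n_ensembles = config[["ensembles"]] %||% 100)
      b <- run_benchmark(config[["methods"]] %||%
                           c("ttest", "catreg-adj", "catreg-rank",
                             "bahsic", "vbpcafe", "cpcafe"),
                         cfg,
                         s_values = config[["s_values"]] %||% c(2, 1, 0.5),
                         seed = seed)
      write.table(b$summary, file.path(out_dir, "summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(b$scores, file.path(out_dir, "scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      c("summary.tsv", "scores.tsv")
    },
    integrate = {
      mirna <- read_expression(config[["mirna"]])
      mrna <- read_expression(config[["mrna"]])
      probe_map <- if (!is.null(config[["probe_map"]]))
        read.delim(config[["probe_map"]]) else NULL
      mirna_seqs <- if (!is.null(config[["mirna_fasta"]]))
        Biostrings::readRNAStringSet(config[["mirna_fasta"]]) else NULL
      utr_seqs <- if (!is.null(config[["utr_fasta"]]))
        Biostrings::readDNAStringSet(config[["utr_fasta"]]) else NULL
      pairs <- integrate_pairs(mirna, mrna,
                               selected_mirna = config[["selected_mirna"]],
                               selected_mrna = config[["selected_mrna"]],
                               mirna_seqs = mirna_seqs,
                               utr_seqs = utr_seqs,
                               probe_map = probe_map)
      write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      "pairs.tsv"
    },
    abort(sprintf("unknown workflow '%s'.", wf)))

  paths <- file.path(out_dir, outputs)
  manifest <- list(workflow = wf, seed = seed,
                   package_version = as.character(packageVersion("pcafe")),
                   parameters = config[setdiff(names(config),
                                               c("workflow", "out_dir"))],
                   outputs = as.list(setNames(
                     as.character(tools::md5sum(paths)), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
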