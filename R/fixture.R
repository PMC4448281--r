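#' Specification of the synthetic miRNA/mRNA fixture
#'
#' Describes a synthetic two-omics study emulating the layout of a stressed
#' mouse heart experiment: 12 conditions (7 treatment, 5 control; stress and
#' rest durations encoded in the condition name as `T<stress>-<rest>d` /
#' `C<stress>-<rest>d`), a fixed number of biological replicates per
#' condition, miRNAs measured by several probes each, and a set of planted
#' miRNA-mRNA pairs that are negatively correlated across samples and whose
#' mRNA 3'UTR contains the 7mer-m8 site of the paired miRNA. The fixture is
#' synthetic throughout; it reproduces the shape of such a data set, not its
#' biology.
#'
#' @param n_replicates Biological replicates per condition (`>= 2`).
#' @param n_mirna Number of distinct miRNAs.
#' @param n_probes_per_mirna Probes measuring each miRNA.
#' @param n_mrna Number of mRNAs.
#' @param n_planted_pairs Number of planted negatively correlated
#'   miRNA-mRNA pairs (`<= min(n_mirna, n_mrna)`).
#' @param effect_size Expected magnitude of the planted negative Pearson
#'   correlation (0-1).
#' @param noise_sd Standard deviation of measurement noise on the log-scale
#'   signal.
#' @param utr_length Length of each synthetic 3'UTR (nt).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_replicates = 4, n_mirna = 20,
                         n_probes_per_mirna = 3, n_mrna = 50,
                         n_planted_pairs = 8, effect_size = 0.8,
                         noise_sd = 0.3, utr_length = 300, seed = 1) {
  if (n_replicates < 2) abort("n_replicates must be >= 2.")
  if (n_planted_pairs > min(n_mirna, n_mrna))
    abort("planted pairs must reference existing miRNA and mRNA IDs.")
  if (effect_size < 0 || effect_size >= 1)
    abort("effect_size must be in [0, 1).")
  structure(list(n_conditions_treatment = 7L, n_conditions_control = 5L,
                 n_replicates = n_replicates, n_mirna = n_mirna,
                 n_probes_per_mirna = n_probes_per_mirna, n_mrna = n_mrna,
                 n_planted_pairs = n_planted_pairs,
                 effect_size = effect_size, noise_sd = noise_sd,
                 utr_length = utr_length, seed = seed),
            class = "fixture_spec")
}

## the 12 study conditions: stress days / rest days; controls are missing
## for 1d and 3d stress with 1d rest
fixture_conditions <- function() {
  treat <- data.frame(stress = c(1, 2, 3, 10, 5, 5, 10),
                      rest = c(1, 1, 1, 1, 1, 10, 42), role = "treatment")
  ctrl <- data.frame(stress = c(2, 10, 5, 5, 10),
                     rest = c(1, 1, 1, 10, 42), role = "control")
  cond <- rbind(treat, ctrl)
  cond$condition <- paste0(ifelse(cond$role == "treatment", "T", "C"),
                           cond$stress, "-", cond$rest, "d")
  cond$pair_id <- paste0(cond$stress, "-", cond$rest, "d")
  paired <- cond$pair_id %in% cond$pair_id[cond$role == "control"]
  cond$pair_id[!paired] <- NA_character_
  cond
}

#' Generate the synthetic miRNA/mRNA fixture
#'
#' Builds two positive-valued expression matrices (log2-scale intensities
#' around a baseline of 8), a condition design table, miRNA and 3'UTR
#' sequence sets, and truth tables for the planted structure.
#'
#' Each sample carries a latent stress activity (condition effect plus
#' replicate noise, unit variance; treatment conditions high, controls low).
#' Planted miRNAs follow the activity positively, their paired mRNAs
#' negatively, with amplitude chosen so the expected Pearson correlation of
#' a planted pair is `-effect_size`. Every miRNA's probes share its signal
#' plus independent probe noise. All other features ride independent latent
#' profiles.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `mirna`, `mrna` (probe-level
#'   [expression_matrix()] objects; miRNA labels are conditions),
#'   `design` (tibble: `sample_id`, `condition`, `role`, `pair_id`,
#'   `replicate`), `mirna_seqs` (`Biostrings::RNAStringSet`), `utr_seqs`
#'   (`Biostrings::DNAStringSet`), `planted_pairs` (tibble: `mirna_id`,
#'   `mrna_id`, `site_offset`), and `probe_map` (tibble: `probe_id`,
#'   `mirna_id`).
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7))
#' ncol(fx$mirna) # 48 samples
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  cond <- fixture_conditions()
  n_rep <- spec$n_replicates
  design <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    data.frame(condition = cond$condition[i], role = cond$role[i],
               pair_id = cond$pair_id[i], replicate = seq_len(n_rep))
  }))
  design$sample_id <- paste0(design$condition, "_r", design$replicate)
  M <- nrow(design)

  ## latent stress activity: condition effect (+/- delta) + replicate noise,
  ## unit total variance
  delta <- 0.7
  cond_eff <- ifelse(design$role == "treatment", delta, -delta)
  z <- cond_eff + rnorm(M, 0, sqrt(1 - delta^2))

  es <- spec$effect_size
  amp <- spec$noise_sd * sqrt(es / (1 - es))

  latent_profile <- function() rnorm(M)

  ## miRNA-level signals
  mirna_ids <- sprintf("mir-%03d", seq_len(spec$n_mirna))
  mrna_ids <- sprintf("gene-%03d", seq_len(spec$n_mrna))
  planted <- seq_len(spec$n_planted_pairs)
  mirna_signal <- matrix(0, spec$n_mirna, M)
  for (i in seq_len(spec$n_mirna)) {
    mirna_signal[i, ] <- if (i %in% planted) amp * z else amp * latent_profile()
  }

  ## probe-level miRNA matrix
  n_probe <- spec$n_mirna * spec$n_probes_per_mirna
  probe_map <- tibble(
    probe_id = sprintf("probe-%04d", seq_len(n_probe)),
    mirna_id = rep(mirna_ids, each = spec$n_probes_per_mirna))
  mirna_vals <- mirna_signal[rep(seq_len(spec$n_mirna),
                                 each = spec$n_probes_per_mirna), ] +
    matrix(rnorm(n_probe * M, 0, spec$noise_sd), n_probe, M)

  ## mRNA matrix: planted genes anti-track the activity
  mrna_vals <- matrix(rnorm(spec$n_mrna * M, 0, spec$noise_sd),
                      spec$n_mrna, M)
  for (g in seq_len(spec$n_mrna)) {
    sig <- if (g %in% planted) -amp * z else amp * latent_profile()
    mrna_vals[g, ] <- mrna_vals[g, ] + sig
  }

  baseline <- 8
  mirna <- expression_matrix(baseline + mirna_vals,
                             feature_ids = probe_map$probe_id,
                             sample_ids = design$sample_id,
                             labels = design$condition)
  mrna <- expression_matrix(baseline + mrna_vals,
                            feature_ids = mrna_ids,
                            sample_ids = design$sample_id,
                            labels = design$condition)

  ## sequences: random 22-nt miRNAs; UTRs with the 7mer-m8 site of the
  ## paired miRNA planted at a random offset
  rna <- c("A", "C", "G", "U")
  dna <- c("A", "C", "G", "T")
  mirna_seq <- vapply(seq_len(spec$n_mirna), function(i)
    paste0(sample(rna, 22, replace = TRUE), collapse = ""), character(1))
  utr_seq <- vapply(seq_len(spec$n_mrna), function(g)
    paste0(sample(dna, spec$utr_length, replace = TRUE), collapse = ""),
    character(1))
  site_offset <- rep(NA_integer_, spec$n_planted_pairs)
  for (p in planted) {
    site <- seed_site_7mer_m8(mirna_seq[p])
    off <- sample.int(spec$utr_length - 7L, 1) # 0-based offset
    substr(utr_seq[p], off + 1L, off + 7L) <- site
    site_offset[p] <- off
  }
  mirna_seqs <- Biostrings::RNAStringSet(setNames(mirna_seq, mirna_ids))
  utr_seqs <- Biostrings::DNAStringSet(setNames(utr_seq, mrna_ids))

  list(mirna = mirna, mrna = mrna, design = as_tibble(design[
         , c("sample_id", "condition", "role", "pair_id", "replicate")]),
       mirna_seqs = mirna_seqs, utr_seqs = utr_seqs,
       planted_pairs = tibble(mirna_id = mirna_ids[planted],
                              mrna_id = mrna_ids[planted],
                              site_offset = site_offset),
       probe_map = probe_map)
}

#' Write a fixture to disk as plain-text files
#'
#' Expression matrices and the design table go to TSV; sequences to FASTA.
#'
#' @param fx A fixture as returned by [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(fx$mirna, file.path(dir, "mirna.tsv"))
  write_expression(fx$mrna, file.path(dir, "mrna.tsv"))
  write.table(fx$design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fx$planted_pairs, file.path(dir, "planted_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fx$probe_map, file.path(dir, "probe_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(fx$mirna_seqs, file.path(dir, "mirna.fa"))
  Biostrings::writeXStringSet(fx$utr_seqs, file.path(dir, "utr.fa"))
  invisible(dir)
}
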