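#' Simulation configuration for the categorical multiclass benchmark
#'
#' Parameters of the Gaussian mixture used to benchmark feature extraction on
#' unordered multiclass data. `N` features by `M` samples; samples fall into
#' `K` equally sized classes; the first `n_prime` features are "distinct"
#' (their means move with the class), the remainder carry no class signal.
#'
#' The class means are equally spaced and symmetric about zero,
#' \eqn{\mu_k = ((k-1)/(K-1) - 1/2) s}. The scale `s` controls class
#' separability: large `s` is the easy regime, small `s` the hard one.
#'
#' @param N Total feature count.
#' @param n_prime Number of class-distinct features (even, `<= N`).
#' @param K Number of classes (`>= 2`).
#' @param M Number of samples (divisible by `K`).
#' @param s Class-separation scale (dimensionless, `>= 0`).
#' @param sigma Gaussian standard deviation of every expression value
#'   (fixed at 0.5 in the benchmark).
#' @param n_ensembles Number of independent ensembles for benchmark runs.
#' @return A `sim_config` list.
#' @examples
#' sim_config(s = 2)
#' @export
sim_config <- function(N = 100, n_prime = 10, K = 4, M = 20, s = 2,
                       sigma = 0.5, n_ensembles = 100) {
  if (K < 2) abort("invalid configuration: K must be >= 2.")
  if (n_prime > N) abort("invalid configuration: n_prime must be <= N.")
  if (n_prime %% 2 != 0) abort("invalid configuration: n_prime must be even.")
  if (M %% K != 0) abort("invalid configuration: M must be divisible by K.")
  if (s < 0) abort("invalid configuration: s must be >= 0.")
  if (sigma <= 0) abort("invalid configuration: sigma must be > 0.")
  structure(list(N = N, n_prime = n_prime, K = K, M = M, s = s,
                 sigma = sigma, n_ensembles = n_ensembles),
            class = "sim_config")
}

#' Class mean of the simulation mixture
#'
#' \eqn{\mu_k = ((k-1)/(K-1) - 1/2) s}: `K` means, equally spaced, symmetric
#' about 0, spanning `[-s/2, s/2]`.
#'
#' @param k Class index (1-based), possibly vectorized.
#' @param K Class count (`>= 2`).
#' @param s Separation scale.
#' @return Numeric vector of class means.
#' @examples
#' class_mean(1:4, K = 4, s = 2) # -1, -1/3, 1/3, 1
#' @export
class_mean <- function(k, K, s) {
  if (K < 2) abort("invalid configuration: K must be >= 2.")
  stopifnot(all(k >= 1), all(k <= K))
  ((k - 1) / (K - 1) - 0.5) * s
}

#' Simulate one categorical multiclass data set
#'
#' Draws an `N x M` expression matrix under the benchmark mixture. Samples
#' are assigned to classes in contiguous blocks of `M/K`. Features
#' `1..n_prime/2` are drawn `N(mu_k, sigma)` in class `k`, features
#' `n_prime/2+1..n_prime` are drawn `N(-mu_k, sigma)` (up- and downregulated
#' genes coexist), and every remaining entry is drawn `N(eps, sigma)` with
#' `eps` resampled uniformly from the class means (`P(eps = mu_k) = 1/K`).
#'
#' With the default `eps_mode = "cell"`, `eps` is redrawn for every entry of
#' a non-distinct feature, which makes the null features variance-matched to
#' the distinct ones (total variance `sigma^2 + 5 s^2/36` for `K = 4`) while
#' carrying no coherent class pattern. `eps_mode = "feature"` draws one
#' offset per feature instead; null features then become constant rows plus
#' noise, a much easier separation problem for variance-seeking methods.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this draw.
#' @param eps_mode `"cell"` (default) or `"feature"`; see Details.
#' @return A list: `data` (an [expression_matrix()] with class labels),
#'   `truth` (indices of the distinct features, `1..n_prime`).
#' @examples
#' d <- simulate_dataset(sim_config(s = 2), seed = 1)
#' dim(d$data); d$truth
#' @export
simulate_dataset <- function(config, seed = NULL,
                             eps_mode = c("cell", "feature")) {
  stopifnot(inherits(config, "sim_config"))
  eps_mode <- match.arg(eps_mode)
  if (!is.null(seed)) set.seed(seed)
  N <- config$N; Np <- config$n_prime; K <- config$K; M <- config$M
  s <- config$s; sg <- config$sigma
  labels <- rep(seq_len(K), each = M / K)
  mus <- class_mean(seq_len(K), K, s)
  X <- matrix(0, N, M)
  if (Np > 0) {
    half <- Np / 2
    for (k in seq_len(K)) {
      j <- which(labels == k)
      if (half > 0)
        X[seq_len(half), j] <- rnorm(half * length(j), mus[k], sg)
      X[half + seq_len(half), j] <- rnorm(half * length(j), -mus[k], sg)
    }
  }
  if (N > Np) {
    n_null <- N - Np
    eps <- if (eps_mode == "cell") {
      matrix(sample(mus, n_null * M, replace = TRUE), n_null, M)
    } else {
      matrix(sample(mus, n_null, replace = TRUE), n_null, M)
    }
    X[(Np + 1):N, ] <- eps + rnorm(n_null * M, 0, sg)
  }
  data <- expression_matrix(X,
                            feature_ids = paste0("feat", seq_len(N)),
                            sample_ids = paste0("sample", seq_len(M)),
                            labels = labels)
  list(data = data, truth = seq_len(Np))
}

#' Mislabeling schemes
#'
#' A mislabel scheme is a `K x K` integer matrix of counts: entry `[k, k']`
#' is the number of samples whose true class is `k` that receive label `k'`.
#' Row sums must match the per-class sample counts; the off-diagonal total is
#' the number of mislabeled samples.
#'
#' `mislabel_scheme()` validates and classes such a matrix.
#' `demo_mislabel_schemes()` returns three schemes for the `K = 4`,
#' `M = 20` benchmark that mislabel 4/20 samples (20%) at true-to-wrong
#' label distances 1, 2 and 3, yielding label correlations 0.92, 0.68 and
#' 0.60 ("little", "medium", "heavy").
#'
#' @param counts `K x K` nonnegative integer matrix.
#' @param class_sizes Optional expected per-class sizes to validate row sums
#'   against.
#' @return A `mislabel_scheme` matrix.
#' @export
mislabel_scheme <- function(counts, class_sizes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("scheme must be square (K x K).")
  if (any(counts < 0) || any(counts != round(counts)))
    abort("scheme counts must be nonnegative integers.")
  if (!is.null(class_sizes) && !all(rowSums(counts) == class_sizes))
    abort("scheme row sums must equal per-class sample counts.")
  structure(counts, class = c("mislabel_scheme", "matrix", "array"))
}

#' @rdname mislabel_scheme
#' @export
demo_mislabel_schemes <- function() {
  from_perm <- function(perm) {
    m <- diag(4L) * 4L
    for (k in 1:4) m[k, perm[k]] <- m[k, perm[k]] + 1L
    mislabel_scheme(m, class_sizes = rep(5L, 4))
  }
  list(little = from_perm(c(2L, 1L, 4L, 3L)),   # adjacent swaps, r = 0.92
       medium = from_perm(c(3L, 4L, 1L, 2L)),   # distance-2 swaps, r = 0.68
       heavy = from_perm(c(4L, 3L, 2L, 1L)))    # label reversal, r = 0.60
}

#' Apply a mislabeling scheme to a label vector
#'
#' Reassigns labels so that exactly `counts[k, k']` samples of true class `k`
#' carry label `k'`; which samples within a class are moved is chosen
#' uniformly at random. The Pearson correlation between the true and
#' modified labels (as integers) is reported alongside, the summary used to
#' characterise mislabeling severity.
#'
#' @param labels True labels (factor or integer-coercible).
#' @param scheme A [mislabel_scheme()].
#' @param seed Optional integer seed.
#' @return A list: `labels` (modified, same type ordering as input levels),
#'   `r` (Pearson correlation of true vs modified integer labels).
#' @examples
#' labs <- rep(1:4, each = 5)
#' apply_mislabeling(labs, demo_mislabel_schemes()$heavy, seed = 1)$r
#' @export
apply_mislabeling <- function(labels, scheme, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- factor(labels)
  K <- nlevels(f)
  if (nrow(scheme) != K) abort("scheme dimension must equal class count.")
  true_int <- as.integer(f)
  sizes <- tabulate(true_int, K)
  if (!all(rowSums(scheme) == sizes))
    abort("infeasible scheme: row sums must equal per-class sample counts.")
  new_int <- true_int
  for (k in seq_len(K)) {
    members <- sample(which(true_int == k))
    new_int[members] <- rep(seq_len(K), times = scheme[k, ])
  }
  list(labels = factor(levels(f)[new_int], levels = levels(f)),
       r = cor(true_int, new_int))
}
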