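# Gamma means (in SD units on the log-expression scale) behind the three
# named noise regimes, at the default signal amplitude of 1.0. Chosen once by
# the calibration described in the methods vignette: "low" sits well inside
# the separable regime for every grid cell, "medium" near the boundary of the
# hardest cells, "high" beyond it for most cells.
.tau_presets <- c(low = 0.15, medium = 0.22, high = 0.65)

#' Configuration for one simulated expression data set
#'
#' Describes a cluster-structured log-expression matrix: `k` clusters of
#' (near-)equal size, a disjoint block of signature features per cluster
#' shifted by `signal_amplitude` with a random sign per feature, and
#' additive Gaussian noise `Y = S + eps` with `eps ~ N(nu, tau_g)` where the
#' per-feature noise SD `tau_g` is gamma-distributed with mean `tau_mean`
#' and shape `tau_shape`.
#'
#' @param k Number of clusters (>= 2).
#' @param n_samples Number of samples before scaling.
#' @param n_features Number of features (genes) before scaling.
#' @param noise_level `"low"`, `"medium"` or `"high"`; picks `tau_mean` from
#'   the calibrated presets unless `tau_mean` is given explicitly.
#' @param signature_fraction Fraction of features that carry cluster signal
#'   (default 0.10), split into one block per cluster.
#' @param signal_amplitude Absolute log-scale shift of a signature feature in
#'   its cluster (default 1.0); the sign is random per feature.
#' @param nu Mean of the additive noise (default 0.1).
#' @param tau_mean Mean of the gamma distribution of per-feature noise SDs;
#'   `NULL` (default) uses the preset for `noise_level`.
#' @param tau_shape Gamma shape parameter (default 2).
#' @param seed Integer seed; the realized matrix is a deterministic function
#'   of the config.
#' @param scale Multiplicative down-scaling of `n_samples` and `n_features`
#'   for desk-scale runs (default 1).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(k, n_samples, n_features,
                              noise_level = c("low", "medium", "high"),
                              signature_fraction = 0.10,
                              signal_amplitude = 1.0,
                              nu = 0.1, tau_mean = NULL, tau_shape = 2.0,
                              seed = 1L, scale = 1.0) {
  noise_level <- match.arg(noise_level)
  if (is.null(tau_mean)) tau_mean <- unname(.tau_presets[noise_level])
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (signature_fraction <= 0 || signature_fraction > 1)
    stop("signature_fraction must be in (0, 1]", call. = FALSE)
  if (tau_mean <= 0 || tau_shape <= 0)
    stop("tau_mean and tau_shape must be positive", call. = FALSE)
  if (scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]", call. = FALSE)
  n <- as.integer(round(n_samples * scale))
  f <- as.integer(round(n_features * scale))
  if (n < k)
    stop("scaled n_samples (", n, ") below the number of clusters (", k, ")",
         call. = FALSE)
  structure(list(k = k, n_samples = n, n_features = f,
                 noise_level = noise_level,
                 signature_fraction = signature_fraction,
                 signal_amplitude = signal_amplitude,
                 nu = nu, tau_mean = tau_mean, tau_shape = tau_shape,
                 seed = as.integer(seed), scale = scale),
            class = "simulation_config")
}

#' Simulate a cluster-structured log-expression data set
#'
#' Realizes the generative model of [simulation_config()]:
#' \enumerate{
#'   \item a base log-expression mean per feature, `N(6, 2)` — common to all
#'     samples, so it carries no cluster information;
#'   \item `k` disjoint signature blocks of
#'     `ceiling(signature_fraction * F / k)` features each; the samples of
#'     cluster `c` are shifted by `+/- signal_amplitude` on block `c`, the
#'     sign drawn once per feature;
#'   \item samples assigned to clusters as evenly as possible;
#'   \item per-feature noise SD `tau_g ~ Gamma(shape, mean = tau_mean)` and
#'     elementwise noise `eps ~ N(nu, tau_g)` added to the signal.
#' }
#' Bit-identical output for identical configs (the seed is part of the
#' config).
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_dataset` with fields `X` (observed
#'   matrix, samples x features), `S` (noise-free signal), `truth` (integer
#'   cluster labels), `tau` (realized per-feature noise SDs) and `config`.
#' @examples
#' d <- simulate_dataset(simulation_config(3, 60, 200, "low", seed = 7))
#' table(d$truth)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  f <- config$n_features
  k <- config$k
  set.seed(config$seed)
  truth <- rep_len(seq_len(k), n)
  mu <- stats::rnorm(f, mean = 6, sd = 2)
  S <- matrix(mu, nrow = n, ncol = f, byrow = TRUE)
  block <- ceiling(config$signature_fraction * f / k)
  if (block * k > f)
    stop("signature blocks exceed the number of features", call. = FALSE)
  sig_idx <- sample.int(f, block * k)
  for (c in seq_len(k)) {
    feats <- sig_idx[((c - 1L) * block + 1L):(c * block)]
    signs <- sample(c(-1, 1), block, replace = TRUE)
    S[truth == c, feats] <- S[truth == c, feats] +
      rep(signs * config$signal_amplitude, each = sum(truth == c))
  }
  tau <- stats::rgamma(f, shape = config$tau_shape,
                       rate = config$tau_shape / config$tau_mean)
  eps <- matrix(stats::rnorm(n * f, mean = config$nu,
                             sd = rep(tau, each = n)),
                nrow = n, ncol = f)
  X <- S + eps
  dimnames(X) <- dimnames(S) <-
    list(paste0("S", seq_len(n)), paste0("G", seq_len(f)))
  structure(list(X = X, S = S, truth = truth, tau = tau, config = config),
            class = "simulated_dataset")
}

#' The 27-combination simulation grid
#'
#' The full study grid over cluster counts (3, 6, 12), sample sizes (600,
#' 1000), feature counts (5000, 10000) and noise levels. The grid is not the
#' complete factorial: for each cluster count, all four size combinations
#' appear at low and at medium noise, while high noise appears only at the
#' largest size (1000 samples, 10000 features) — 9 combinations per cluster
#' count, 27 in all. Each combination is repeated `replicates` times with
#' distinct child seeds derived from `seed`.
#'
#' @param scale Down-scaling factor applied to every config's sample and
#'   feature counts (default 1 = full size).
#' @param replicates Replicate simulations per combination (default 1).
#' @param seed Root seed from which each config's seed is derived.
#' @param ... Further arguments passed to [simulation_config()] (e.g.
#'   `signal_amplitude`).
#' @return A list of `27 * replicates` [simulation_config()] objects.
#' @export
simulation_grid <- function(scale = 1.0, replicates = 1L, seed = 1L, ...) {
  sizes <- list(c(1000L, 10000L), c(1000L, 5000L),
                c(600L, 10000L), c(600L, 5000L))
  rows <- list()
  for (k in c(12L, 3L, 6L)) {
    rows[[length(rows) + 1L]] <- list(k = k, noise = "high",
                                      n = 1000L, f = 10000L)
    for (noise in c("low", "medium"))
      for (sz in sizes)
        rows[[length(rows) + 1L]] <- list(k = k, noise = noise,
                                          n = sz[1L], f = sz[2L])
  }
  set.seed(seed)
  child <- matrix(sample.int(.Machine$integer.max, length(rows) * replicates),
                  nrow = length(rows))
  configs <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    for (rep in seq_len(replicates)) {
      cfg <- simulation_config(k = r$k, n_samples = r$n, n_features = r$f,
                               noise_level = r$noise, seed = child[i, rep],
                               scale = scale, ...)
      cfg$grid_row <- i
      cfg$replicate <- rep
      configs[[length(configs) + 1L]] <- cfg
    }
  }
  configs
}

#' Write a simulated data set to plain-text files
#'
#' Writes `<prefix>.matrix.tsv` (observed matrix), `<prefix>.truth.tsv`
#' (sample id and truth label) and `<prefix>.config.json`-style TSV of the
#' config fields, so downstream stages can run without regeneration.
#'
#' @param dataset A `simulated_dataset`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  mp <- paste0(prefix, ".matrix.tsv")
  tp <- paste0(prefix, ".truth.tsv")
  cp <- paste0(prefix, ".config.tsv")
  write_matrix_file(dataset$X, mp)
  utils::write.table(
    data.frame(sample_id = rownames(dataset$X), cluster = dataset$truth),
    tp, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  utils::write.table(
    data.frame(field = names(cfg),
               value = vapply(cfg, function(v) as.character(v)[1L],
                              character(1L))),
    cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mp, tp, cp))
}
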