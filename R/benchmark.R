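#' Baseline clustering methods
#'
#' Runs one of the standard algorithms the refinement heuristic is compared
#' against, each delegated to its established implementation:
#' Ward-linkage agglomeration (`stats::hclust`, `ward.D2`, cut at `k`) on
#' the distance matrix; `stats::kmeans` on the feature matrix (10 restarts);
#' partitioning around medoids (`cluster::pam`) on the distance matrix;
#' `cluster::clara` and spectral clustering (`kernlab::specc`) on the
#' feature matrix; and the standalone random-start heuristic
#' ([sillyputty_random()]). This function is orchestration only.
#'
#' @param method One of `"hierarchical_ward"`, `"kmeans"`, `"pam"`,
#'   `"clara"`, `"spectral"`, `"sillyputty_random"`.
#' @param X Feature matrix (samples x features); may be `NULL` for the
#'   distance-based methods.
#' @param D Distance matrix; may be `NULL` for the feature-based methods.
#' @param k Number of clusters.
#' @param seed Seed fixed before any stochastic method runs.
#' @param n_starts Random starts for `sillyputty_random` (default 20).
#' @return Integer cluster labels, one per sample.
#' @export
run_baseline <- function(method, X = NULL, D = NULL, k, seed = 1L,
                         n_starts = 20L) {
  need <- function(obj, what)
    if (is.null(obj)) stop("method '", method, "' needs ", what,
                           call. = FALSE)
  set.seed(seed)
  switch(method,
    hierarchical_ward = {
      need(D, "a distance matrix")
      stats::cutree(stats::hclust(stats::as.dist(D), method = "ward.D2"), k)
    },
    kmeans = {
      need(X, "a feature matrix")
      stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)$cluster
    },
    pam = {
      need(D, "a distance matrix")
      cluster::pam(stats::as.dist(D), k, cluster.only = TRUE)
    },
    clara = {
      need(X, "a feature matrix")
      cluster::clara(X, k)$clustering
    },
    spectral = {
      need(X, "a feature matrix")
      as.integer(kernlab::specc(as.matrix(X), centers = k))
    },
    sillyputty_random = {
      need(D, "a distance matrix")
      cfg <- sillyputty_config(n_starts = n_starts, seed = seed)
      sillyputty_random(D, k, cfg)$labels
    },
    stop_unavailable(method)
  )
}

stop_unavailable <- function(method) {
  cond <- structure(
    class = c("puttyclust_unavailable", "error", "condition"),
    list(message = paste0("clustering method '", method,
                          "' is not available"),
         call = NULL))
  stop(cond)
}

#' The default method roster of the comparison study
#'
#' Five standalone baselines, the standalone random-start heuristic, and one
#' warm-start hybrid per baseline (`"hybrid:<base>"`).
#'
#' @return Character vector of method names accepted by [run_benchmark()].
#' @export
benchmark_methods <- function() {
  bases <- c("hierarchical_ward", "kmeans", "pam", "clara", "spectral")
  c(bases, "sillyputty_random", paste0("hybrid:", bases))
}

#' Run the method comparison over a grid of simulated data sets
#'
#' For every config in `grid`: simulate the data set, compute Euclidean
#' distances, run every requested method (hybrids take the base method's
#' labels from the same data set as a warm start for [sillyputty_warm()]),
#' and score all five validity indices against the ground truth. Per-cell
#' failures (e.g. a degenerate clustering) are recorded as `NA` rows, not
#' fatal. With `cache_dir` set, finished cells are written to disk and
#' reloaded on re-run, keyed by config seed, dimensions and method.
#'
#' @param grid List of [simulation_config()]s, e.g. from [simulation_grid()].
#' @param methods Character vector of method names; see
#'   [benchmark_methods()]. A hybrid's base is added automatically if absent.
#' @param n_starts Random starts for the standalone heuristic (default 20).
#' @param sp_config A [sillyputty_config()] used for warm starts (the seed
#'   field is ignored; per-cell seeds are derived from each config's seed).
#' @param cache_dir Directory for per-cell result caching, or `NULL` (off).
#' @param verbose Print one line per data set.
#' @return A list of class `benchmark_table`: `cells` (one row per data set
#'   x method with the five indices), `summary` (per-method means of ASW,
#'   ARI, NWSS, entropy, plus the perfect classification count `pcc` and
#'   `n_datasets`), and `by_config` (per grid-row x method means across
#'   replicates).
#' @export
run_benchmark <- function(grid, methods = benchmark_methods(),
                          n_starts = 20L,
                          sp_config = sillyputty_config(),
                          cache_dir = NULL, verbose = FALSE) {
  stopifnot(length(grid) > 0L, length(methods) > 0L)
  hybrids <- methods[startsWith(methods, "hybrid:")]
  bases_needed <- unique(c(sub("^hybrid:", "", hybrids),
                           setdiff(methods, hybrids)))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (gi in seq_along(grid)) {
    cfg <- grid[[gi]]
    ds <- simulate_dataset(cfg)
    D <- euclidean_distances(ds$X)
    base_labels <- list()
    for (m in bases_needed) {
      seed_m <- derive_seed(cfg$seed, m)
      base_labels[[m]] <- tryCatch(
        run_baseline(m, X = ds$X, D = D, k = cfg$k, seed = seed_m,
                     n_starts = n_starts),
        error = function(e) e)
    }
    for (m in methods) {
      key <- sprintf("cell_%d_%d_%d_%s", cfg$seed, cfg$n_samples,
                     cfg$n_features, gsub("[^a-z_]", "-", m))
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(key, ".rds")) else NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        rows[[length(rows) + 1L]] <- readRDS(cache_file)
        next
      }
      labels <- if (startsWith(m, "hybrid:")) {
        base <- base_labels[[sub("^hybrid:", "", m)]]
        if (inherits(base, "error")) base else tryCatch({
          wcfg <- sp_config
          wcfg$seed <- derive_seed(cfg$seed, m)
          sillyputty_warm(D, base, wcfg)$labels
        }, error = function(e) e)
      } else base_labels[[m]]
      row <- if (inherits(labels, "error")) {
        data.frame(asw = NA_real_, ari = NA_real_, entropy = NA_real_,
                   wss = NA_real_, nwss = NA_real_, perfect = NA,
                   note = conditionMessage(labels))
      } else {
        ev <- evaluate_clustering(labels, ds$truth, X = ds$X, D = D)
        data.frame(asw = ev$asw, ari = ev$ari, entropy = ev$entropy,
                   wss = ev$wss, nwss = ev$nwss, perfect = ev$perfect,
                   note = "")
      }
      row <- cbind(data.frame(grid_row = cfg$grid_row %||% gi,
                              replicate = cfg$replicate %||% 1L,
                              k = cfg$k, noise = cfg$noise_level,
                              n_samples = cfg$n_samples,
                              n_features = cfg$n_features,
                              seed = cfg$seed, method = m,
                              stringsAsFactors = FALSE),
                   row)
      if (!is.null(cache_file)) saveRDS(row, cache_file)
      rows[[length(rows) + 1L]] <- row
    }
    if (verbose)
      message(sprintf("[%d/%d] k=%d noise=%s n=%d F=%d done",
                      gi, length(grid), cfg$k, cfg$noise_level,
                      cfg$n_samples, cfg$n_features))
  }
  cells <- do.call(rbind, rows)
  structure(list(cells = cells,
                 summary = summarize_cells(cells, c("method")),
                 by_config = summarize_cells(cells,
                                             c("grid_row", "k", "noise",
                                               "n_samples", "n_features",
                                               "method"))),
            class = "benchmark_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

derive_seed <- function(seed, label) {
  (as.numeric(seed) * 1009 + sum(utf8ToInt(label)) * 131) %%
    (.Machine$integer.max - 1) + 1
}

summarize_cells <- function(cells, by) {
  keys <- unique(cells[by])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(cells))
    for (col in by) sel <- sel & cells[[col]] == keys[[col]][i]
    sub <- cells[sel, ]
    out[[i]] <- cbind(
      keys[i, , drop = FALSE],
      data.frame(asw = mean(sub$asw, na.rm = TRUE),
                 ari = mean(sub$ari, na.rm = TRUE),
                 nwss = mean(sub$nwss, na.rm = TRUE),
                 entropy = mean(sub$entropy, na.rm = TRUE),
                 pcc = sum(sub$perfect, na.rm = TRUE),
                 n_datasets = nrow(sub)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("Benchmark over %d data sets, %d methods\n",
              length(unique(x$cells$seed)),
              length(unique(x$cells$method))))
  s <- x$summary[order(-x$summary$ari), ]
  s[c("asw", "ari", "nwss", "entropy")] <-
    lapply(s[c("asw", "ari", "nwss", "entropy")], round, 3L)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Write the benchmark aggregate as a tab-separated table
#'
#' @param bench A `benchmark_table`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  utils::write.table(bench$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
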