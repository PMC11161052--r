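#' Control parameters for the silhouette-refinement loop
#'
#' @param max_iter Maximum number of single-sample moves before the run is
#'   cut off (default 1000).
#' @param loop_window Number of recent iterations against which the current
#'   silhouette vector is compared to detect a cycle (default 20).
#' @param n_starts Number of independent random initial partitions used by
#'   [sillyputty_random()] (default 100).
#' @param seed Integer seed making random-start runs reproducible, or `NULL`
#'   to draw from the session RNG state.
#' @return A list of class `sillyputty_config`.
#' @export
sillyputty_config <- function(max_iter = 1000L, loop_window = 20L,
                              n_starts = 100L, seed = NULL) {
  max_iter <- as.integer(max_iter)
  loop_window <- as.integer(loop_window)
  n_starts <- as.integer(n_starts)
  if (max_iter < 1L || loop_window < 1L || n_starts < 1L)
    stop("max_iter, loop_window and n_starts must be positive", call. = FALSE)
  if (loop_window > max_iter)
    stop("loop_window must not exceed max_iter", call. = FALSE)
  structure(list(max_iter = max_iter, loop_window = loop_window,
                 n_starts = n_starts, seed = seed),
            class = "sillyputty_config")
}

#' One refinement step: move the worst-clustered sample
#'
#' Computes the silhouette profile of the current assignment. If every
#' silhouette width is non-negative the labels are a fixed point and are
#' returned unchanged. Otherwise the sample with the most negative width
#' (ties broken by lowest sample index) is reassigned to its nearest foreign
#' cluster — the cluster attaining its separation value `b`.
#'
#' @inheritParams silhouette_profile
#' @return A list with `labels` (possibly updated), `moved` (index of the
#'   reassigned sample, or `NULL` if none), `from`, `to` (cluster ids), and
#'   `profile` (the silhouette profile of the *input* labels).
#' @export
sillyputty_step <- function(D, labels) {
  D <- as_dist_matrix(D)
  st <- .sp_state(unclass(D), labels)
  mv <- .sp_move(labels, st)
  list(labels = mv$labels, moved = mv$moved, from = mv$from, to = mv$to,
       profile = silhouette_profile(D, labels))
}

# silhouette state for the inner loop: no data.frame overhead
.sp_state <- function(Dm, labels) {
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k < 2L)
    stop("clustering degenerate: fewer than 2 clusters", call. = FALSE)
  sw <- .silhouette_core(Dm, match(labels, lv), k)
  list(s = sw$s, neighbor_label = lv[sw$neighbor], asw = mean(sw$s), k = k)
}

# apply the single-sample move implied by state `st`, or report a fixed point
.sp_move <- function(labels, st) {
  if (min(st$s) >= 0)
    return(list(labels = labels, moved = NULL, from = NULL, to = NULL))
  i <- which.min(st$s)                 # first minimum = lowest sample index
  from <- labels[i]
  to <- st$neighbor_label[i]
  if (sum(labels == from) == 1L && st$k == 2L)
    stop_degenerate(i, from)
  labels[i] <- to
  list(labels = labels, moved = i, from = from, to = to)
}

stop_degenerate <- function(i, from, trace = NULL) {
  cond <- structure(
    class = c("puttyclust_degenerate", "error", "condition"),
    list(message = sprintf(
           "clustering degenerate: moving sample %d would empty cluster '%s' leaving a single cluster",
           i, as.character(from)),
         call = NULL, trace = trace))
  stop(cond)
}

#' Refine a clustering by iterative silhouette optimization
#'
#' The SillyPutty heuristic. Starting from any assignment of samples to at
#' least two clusters, each iteration recomputes all silhouette widths and
#' moves the sample with the most negative width to its nearest foreign
#' cluster. The loop halts when (a) all widths are non-negative
#' (`converged`), (b) `max_iter` moves have been made (`max_iter`), or
#' (c) the current silhouette vector, rounded to 1e-12, already occurred
#' within the last `loop_window` iterations (`cycle_detected`). On cycle or
#' cap termination the iterate with the highest mean silhouette width seen
#' during the run is returned. Clusters may empty during the run (the
#' heuristic can merge); an error of class `puttyclust_degenerate` is raised
#' only if a move would leave a single cluster.
#'
#' @inheritParams silhouette_profile
#' @param init Initial cluster assignment with at least two distinct labels.
#' @param config A [sillyputty_config()].
#' @return A list of class `sillyputty_result`: `labels` (final assignment,
#'   named by sample id), `profile` ([silhouette_profile()] of the final
#'   labels), `asw`, `n_iterations`, `termination` (one of `"converged"`,
#'   `"max_iter"`, `"cycle_detected"`), `initial_asw`, and `trace`, a data
#'   frame with one row per move (`iteration`, `sample`, `from`, `to`,
#'   `min_sil`, `asw` of the state that triggered the move).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' D <- euclidean_distances(X)
#' res <- run_sillyputty(D, sample(1:2, 40, TRUE))
#' res$termination
#' @export
run_sillyputty <- function(D, init, config = sillyputty_config()) {
  D <- as_dist_matrix(D)
  Dm <- unclass(D)
  n <- nrow(Dm)
  if (length(init) != n)
    stop("length of init (", length(init),
         ") does not match number of samples (", n, ")", call. = FALSE)
  labels <- init
  ring <- vector("list", 0L)
  best <- NULL
  trace <- vector("list", 0L)
  iter <- 0L
  termination <- NULL
  repeat {
    st <- .sp_state(Dm, labels)
    if (is.null(best) || st$asw > best$asw)
      best <- list(labels = labels, asw = st$asw)
    if (min(st$s) >= 0) {
      termination <- "converged"
      final_labels <- labels
      break
    }
    key <- round(st$s, 12L)
    if (any(vapply(ring, identical, logical(1L), y = key))) {
      termination <- "cycle_detected"
      final_labels <- best$labels
      break
    }
    if (iter >= config$max_iter) {
      termination <- "max_iter"
      final_labels <- best$labels
      break
    }
    ring <- c(ring, list(key))
    if (length(ring) > config$loop_window)
      ring <- ring[-1L]
    mv <- tryCatch(.sp_move(labels, st),
                   puttyclust_degenerate = function(e) {
                     e$trace <- do.call(rbind, trace)
                     stop(e)
                   })
    iter <- iter + 1L
    trace[[iter]] <- data.frame(iteration = iter, sample = mv$moved,
                                from = as.character(mv$from),
                                to = as.character(mv$to),
                                min_sil = min(st$s), asw = st$asw,
                                stringsAsFactors = FALSE)
    labels <- mv$labels
  }
  profile <- silhouette_profile(D, final_labels)
  names(final_labels) <- rownames(Dm)
  structure(list(labels = final_labels,
                 profile = profile,
                 asw = attr(profile, "asw"),
                 n_iterations = iter,
                 termination = termination,
                 initial_asw = if (iter > 0L) trace[[1L]]$asw else attr(profile, "asw"),
                 trace = if (iter > 0L) do.call(rbind, trace) else
                   data.frame(iteration = integer(), sample = integer(),
                              from = character(), to = character(),
                              min_sil = numeric(), asw = numeric())),
            class = "sillyputty_result")
}

#' Standalone clustering from random starts
#'
#' Runs the refinement loop from `n_starts` independent random partitions
#' into `k` clusters (one sample dealt to each cluster first, so no start has
#' an empty cluster) and returns the result with the highest final mean
#' silhouette width. Fully deterministic given `config$seed`: a root seed
#' spawns one child seed per start.
#'
#' @inheritParams run_sillyputty
#' @param k Number of clusters to seek; `2 <= k <= n`.
#' @return The best `sillyputty_result`, with an extra field `start` giving
#'   the index of the winning random start.
#' @export
sillyputty_random <- function(D, k, config = sillyputty_config()) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("more clusters (", k, ") than samples (", n, ")",
                  call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max, config$n_starts)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    set.seed(child_seeds[s])
    init <- random_partition(n, k)
    res <- run_sillyputty(D, init, config)
    if (is.null(best) || res$asw > best$asw) {
      best <- res
      best$start <- s
    }
  }
  best
}

# uniform random partition of n samples into k non-empty clusters:
# deal one sample per cluster, assign the rest uniformly
random_partition <- function(n, k) {
  init <- sample.int(k, n, replace = TRUE)
  init[sample.int(n, k)] <- seq_len(k)
  init
}

#' Warm-start refinement of another method's clustering
#'
#' Identical to [run_sillyputty()]; exists as a named entry point so that
#' hybrid runs (e.g. Ward hierarchical clustering followed by silhouette
#' refinement) are distinguishable in benchmark reports.
#'
#' @inheritParams run_sillyputty
#' @param init Cluster labels produced by another algorithm.
#' @return A `sillyputty_result` with field `warm_start = TRUE`.
#' @export
sillyputty_warm <- function(D, init, config = sillyputty_config()) {
  res <- run_sillyputty(D, init, config)
  res$warm_start <- TRUE
  res
}

#' @export
print.sillyputty_result <- function(x, ...) {
  cat("Silhouette-refined clustering\n")
  cat(sprintf("  samples: %d   clusters: %d\n",
              length(x$labels), length(unique(x$labels))))
  cat(sprintf("  ASW: %.4f (initial %.4f)\n", x$asw, x$initial_asw))
  cat(sprintf("  iterations: %d   termination: %s\n",
              x$n_iterations, x$termination))
  invisible(x)
}
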