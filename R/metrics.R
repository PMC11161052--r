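#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement. Computed from the contingency
#' table of the two labelings:
#' `ARI = (S_ij - S_a S_b / C(n,2)) / ((S_a + S_b)/2 - S_a S_b / C(n,2))`
#' where `S_ij`, `S_a`, `S_b` sum `C(m, 2)` over the table cells, row sums
#' and column sums. Equals 1 exactly when the partitions are identical up to
#' relabeling; has expected value 0 for independent random partitions.
#'
#' @param p,t Two label vectors of equal length (any atomic type).
#' @return A single number `<= 1`.
#' @export
adjusted_rand_index <- function(p, t) {
  if (length(p) != length(t))
    stop("label vectors differ in length (", length(p), " vs ", length(t), ")",
         call. = FALSE)
  if (length(p) == 0L) stop("empty label vectors", call. = FALSE)
  tab <- table(p, t)
  n <- length(p)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sij <- comb2(tab)
  sa <- comb2(rowSums(tab))
  sb <- comb2(colSums(tab))
  n2 <- n * (n - 1) / 2
  expected <- sa * sb / n2
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sij - expected) / denom
}

#' Normalized clustering entropy against a reference partition
#'
#' Measures the impurity of each predicted cluster with respect to the truth
#' labels. For a predicted cluster `S` holding `n_j` samples of truth class
#' `j`, its entropy is `-(1/log K) * sum_j (n_j/|S|) log(n_j/|S|)` with
#' `K` the number of truth classes and `0 log 0 = 0`; the global value is the
#' size-weighted mean over predicted clusters. Ranges over \[0, 1\]: 0 when
#' every predicted cluster is pure, 1 when every cluster contains all truth
#' classes in equal proportion. The log base cancels against the normalizer.
#'
#' @param p Predicted cluster labels.
#' @param t Ground-truth labels; at least two distinct classes.
#' @return A single number in \[0, 1\].
#' @export
cluster_entropy <- function(p, t) {
  if (length(p) != length(t))
    stop("label vectors differ in length (", length(p), " vs ", length(t), ")",
         call. = FALSE)
  K <- length(unique(t))
  if (K < 2L)
    stop("entropy undefined for a single truth class (log K = 0)",
         call. = FALSE)
  n <- length(p)
  total <- 0
  for (cl in unique(p)) {
    in_cl <- p == cl
    size <- sum(in_cl)
    prop <- tabulate(factor(t[in_cl], levels = unique(t))) / size
    prop <- prop[prop > 0]
    e <- -sum(prop * log(prop)) / log(K)
    total <- total + (size / n) * e
  }
  total
}

#' Within-group sum of squares
#'
#' Sum over clusters of squared Euclidean distances from each sample to its
#' cluster centroid — the k-means objective.
#'
#' @param X Numeric matrix, samples in rows.
#' @param labels Cluster assignment aligned with the rows of `X`.
#' @return A single non-negative number.
#' @export
wss <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels))
    stop("labels do not align with rows of X", call. = FALSE)
  total <- 0
  for (cl in unique(labels)) {
    xs <- X[labels == cl, , drop = FALSE]
    mu <- colMeans(xs)
    total <- total + sum(sweep(xs, 2L, mu)^2)
  }
  total
}

#' Normalized within-group sum of squares
#'
#' [wss()] of the candidate labels divided by [wss()] of the ground-truth
#' labels, making the index comparable across data sets of different size.
#' Equals 1 when the candidate matches the truth; values above 1 indicate
#' looser clusters than the truth.
#'
#' @inheritParams wss
#' @param truth Ground-truth labels with strictly positive WSS.
#' @return A single positive number.
#' @export
normalized_wss <- function(X, labels, truth) {
  denom <- wss(X, truth)
  if (denom == 0)
    stop("WSS of the truth labels is zero; normalization undefined",
         call. = FALSE)
  wss(X, labels) / denom
}

#' Does a partition recover the truth exactly?
#'
#' `TRUE` iff the two partitions are identical up to relabeling, checked as
#' `|ARI - 1| <= tol` to absorb floating-point error. Counting these over a
#' batch of simulations gives the perfect classification count.
#'
#' @inheritParams adjusted_rand_index
#' @param tol Tolerance on `ARI = 1` (default `1e-12`).
#' @return A single logical.
#' @export
perfect_classification <- function(p, t, tol = 1e-12) {
  abs(adjusted_rand_index(p, t) - 1) <= tol
}

#' Full evaluation report for one clustering solution
#'
#' Bundles the external indices (adjusted Rand index, normalized entropy,
#' perfect-recovery flag) with the internal ones (mean silhouette width,
#' within-group sum of squares and its truth-normalized form) for a single
#' predicted partition against the ground truth.
#'
#' @param pred Predicted cluster labels.
#' @param truth Ground-truth labels.
#' @param X Feature matrix (samples x features); needed for `wss`/`nwss`,
#'   `NA` otherwise.
#' @param D Distance matrix; needed for `asw` (computed from `X` by
#'   [euclidean_distances()] when `D` is `NULL` and `X` is given).
#' @return A list of class `evaluation_report` with fields `asw`, `ari`,
#'   `entropy`, `wss`, `nwss`, `perfect`.
#' @export
evaluate_clustering <- function(pred, truth, X = NULL, D = NULL) {
  if (is.null(D) && !is.null(X)) D <- euclidean_distances(X)
  asw <- if (!is.null(D) && length(unique(pred)) >= 2L)
    mean_silhouette(D, pred) else NA_real_
  w <- if (!is.null(X)) wss(X, pred) else NA_real_
  nw <- if (!is.null(X)) normalized_wss(X, pred, truth) else NA_real_
  structure(list(asw = asw,
                 ari = adjusted_rand_index(pred, truth),
                 entropy = cluster_entropy(pred, truth),
                 wss = w,
                 nwss = nw,
                 perfect = perfect_classification(pred, truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "ASW %.4f | ARI %.4f | Entropy %.4f | NWSS %s | perfect: %s\n",
    x$asw, x$ari, x$entropy,
    if (is.na(x$nwss)) "NA" else sprintf("%.4f", x$nwss),
    x$perfect))
  invisible(x)
}
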