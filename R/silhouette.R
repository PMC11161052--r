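#' Per-sample silhouette profile
#'
#' For each sample computes cohesion `a` (mean distance to the other members
#' of its own cluster), separation `b` (the smallest mean distance to the
#' members of any foreign cluster), the silhouette width
#' `s = (b - a) / max(a, b)`, and the identity of the nearest foreign
#' cluster. Samples alone in their cluster get `s = 0` with `a = NA`
#' (Rousseeuw's convention, matching `cluster::silhouette`); the mean
#' silhouette width averages over all samples including those zeros.
#'
#' @param D Symmetric distance matrix (or `dist` object) over the samples.
#' @param labels Cluster assignment, one label per sample in the row order of
#'   `D`; at least two distinct clusters must be present.
#' @return A data frame of class `silhouette_profile` with one row per
#'   sample and columns `cluster`, `neighbor` (nearest foreign cluster),
#'   `a`, `b`, `sil_width`, plus attribute `asw` (mean of `sil_width`).
#' @examples
#' D <- euclidean_distances(cbind(x = c(0, 1, 10, 11)))
#' p <- silhouette_profile(D, c("A", "A", "B", "B"))
#' attr(p, "asw")  # 0.8997
#' @export
silhouette_profile <- function(D, labels) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (length(labels) != n)
    stop("length of labels (", length(labels),
         ") does not match number of samples (", n, ")", call. = FALSE)
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k < 2L)
    stop("silhouette needs at least 2 clusters (k = ", k, ")", call. = FALSE)
  code <- match(labels, lv)
  sw <- .silhouette_core(unclass(D), code, k)
  out <- data.frame(cluster  = labels,
                    neighbor = lv[sw$neighbor],
                    a        = sw$a,
                    b        = sw$b,
                    sil_width = sw$s,
                    row.names = rownames(D),
                    stringsAsFactors = FALSE)
  attr(out, "asw") <- mean(sw$s)
  class(out) <- c("silhouette_profile", "data.frame")
  out
}

#' Mean silhouette width (ASW)
#'
#' Unweighted arithmetic mean of the per-sample silhouette widths, the
#' internal quality index the refinement heuristic maximizes. Singleton
#' clusters contribute 0. Scale invariant: multiplying all dissimilarities by
#' a positive constant leaves every silhouette, and hence the mean, unchanged.
#'
#' @inheritParams silhouette_profile
#' @return A single number in \[-1, 1\].
#' @export
mean_silhouette <- function(D, labels) {
  attr(silhouette_profile(D, labels), "asw")
}

# Vectorized silhouette engine: D plain numeric matrix, code integer in 1..k.
# Sums[i, c] = total distance from sample i to members of cluster c, obtained
# by one matrix product; everything else is elementwise.
.silhouette_core <- function(D, code, k) {
  n <- length(code)
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), code)] <- 1
  cnt <- colSums(Z)
  Sums <- D %*% Z
  own <- cbind(seq_len(n), code)
  a <- Sums[own] / (cnt[code] - 1)   # divisor m - 1: self excluded
  a[cnt[code] == 1L] <- NA_real_
  M <- sweep(Sums, 2L, cnt, "/")     # mean distance to each cluster
  M[own] <- Inf                      # mask own cluster for the b-minimum
  neighbor <- max.col(-M, ties.method = "first")  # lowest cluster id on ties
  b <- M[cbind(seq_len(n), neighbor)]
  s <- (b - a) / pmax(a, b)
  s[is.na(a)] <- 0                   # singleton convention
  list(a = a, b = b, s = s, neighbor = neighbor)
}

# Accept dist objects or numeric matrices; validate either way.
as_dist_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (inherits(D, "dist_matrix")) return(D)
  validate_distance_matrix(D)
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat(sprintf("Silhouette profile: %d samples, %d clusters, ASW = %.4f\n",
              nrow(x), length(unique(x$cluster)), attr(x, "asw")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Export a silhouette profile as tab-separated text
#'
#' Columns: sample id, assigned cluster, nearest foreign cluster, silhouette
#' width — mirroring the layout of the classic silhouette object.
#'
#' @param profile A `silhouette_profile`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_silhouette_tsv <- function(profile, path) {
  df <- data.frame(sample_id = rownames(profile),
                   cluster   = profile$cluster,
                   neighbor  = profile$neighbor,
                   sil_width = profile$sil_width)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
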