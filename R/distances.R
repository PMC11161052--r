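#' Pairwise Euclidean distances between samples
#'
#' Computes the full symmetric matrix of Euclidean distances between the rows
#' (samples) of a feature matrix. This is the distance the refinement
#' algorithm and the simulated-data benchmarks use throughout.
#'
#' @param X Numeric matrix, samples in rows, features in columns. Row names
#'   (sample ids) are carried over to the result; missing values are rejected.
#' @return A symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal and `dimnames` equal to the sample ids.
#' @examples
#' X <- rbind(a = c(0, 0), b = c(3, 4))
#' euclidean_distances(X)["a", "b"]  # 5
#' @export
euclidean_distances <- function(X) {
  X <- as_feature_matrix(X)
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  validate_distance_matrix(D)
}

#' Pairwise correlation distances between samples
#'
#' Distance between two samples is one minus the Pearson correlation of their
#' feature vectors, the metric commonly used for transcriptome profiles.
#' Values lie in \[0, 2\]: 0 for perfectly correlated samples, 2 for perfectly
#' anti-correlated ones. Correlation is invariant under per-sample affine
#' rescaling with positive slope, so the distance is too.
#'
#' @inheritParams euclidean_distances
#' @return A symmetric `dist_matrix` with entries in \[0, 2\].
#' @export
correlation_distances <- function(X) {
  X <- as_feature_matrix(X)
  if (ncol(X) < 2L)
    stop("correlation distance needs at least 2 features", call. = FALSE)
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(X)[which(v == 0)]
    stop("zero-variance sample row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  D <- 1 - stats::cor(t(X))
  diag(D) <- 0
  D[D < 0] <- 0  # clip -eps roundoff from cor() near +/-1
  dimnames(D) <- list(rownames(X), rownames(X))
  validate_distance_matrix(D)
}

#' Validate (and gently repair) a distance matrix
#'
#' Checks that `D` is a square numeric matrix with no missing values, no
#' negative entries, and asymmetry at most `tol`. Asymmetry below `tol`
#' (typical of decimal text round-trips) is silently repaired by averaging
#' `(D + t(D)) / 2`; the diagonal is forced to exact zero. Anything worse is
#' an error.
#'
#' @param D Square numeric matrix of pairwise dissimilarities.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-6`).
#' @return The repaired matrix, classed `dist_matrix`.
#' @export
validate_distance_matrix <- function(D, tol = 1e-6) {
  if (!is.matrix(D) || !is.numeric(D))
    stop("distance matrix must be a numeric matrix", call. = FALSE)
  if (nrow(D) != ncol(D))
    stop("distance matrix must be square", call. = FALSE)
  if (anyNA(D))
    stop("distance matrix contains missing (NA/NaN) values", call. = FALSE)
  asym <- max(abs(D - t(D)))
  if (asym > tol)
    stop(sprintf("distance matrix asymmetric beyond tolerance (%.3g > %.3g)",
                 asym, tol), call. = FALSE)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (any(D < 0))
    stop("distance matrix has negative entries", call. = FALSE)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("S", seq_len(nrow(D))),
                        paste0("S", seq_len(nrow(D))))
  class(D) <- c("dist_matrix", "matrix", "array")
  D
}

# Coerce to a validated samples x features matrix with unique row names.
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("feature matrix must be a numeric matrix or data frame", call. = FALSE)
  if (anyNA(X))
    stop("feature matrix contains missing (NA/NaN) values", call. = FALSE)
  if (nrow(X) < 2L)
    stop("feature matrix needs at least 2 samples", call. = FALSE)
  if (ncol(X) < 1L)
    stop("feature matrix needs at least 1 feature", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X)))
    stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("feature ids must be unique", call. = FALSE)
  X
}

#' Read a feature or distance matrix from delimited text
#'
#' First column holds sample ids, header row holds feature ids (or sample ids
#' again for a distance matrix). The delimiter is taken from the file
#' extension (`.csv` = comma, anything else = tab) unless given explicitly.
#'
#' @param path File path.
#' @param sep Field delimiter; `NULL` (default) auto-detects from extension.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_file <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a matrix as delimited text (inverse of [read_matrix_file()])
#'
#' @param M Matrix with row names (sample ids).
#' @param path Destination path; extension picks the delimiter.
#' @param sep Field delimiter; `NULL` auto-detects from extension.
#' @return `path`, invisibly.
#' @export
write_matrix_file <- function(M, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
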