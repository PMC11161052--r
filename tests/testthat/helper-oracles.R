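# Independent reference implementations used to pin down expected values.
# All are deliberately naive (explicit loops, no shared code with the
# package internals).

# Triple-loop silhouette reference: for each sample, mean distance to every
# cluster by explicit iteration over pairs.
oracle_silhouette <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- sort(unique(labels))
  a <- b <- s <- numeric(n)
  neighbor <- labels
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    a[i] <- if (length(mates) == 0L) NA_real_ else {
      tot <- 0
      for (j in mates) tot <- tot + D[i, j]
      tot / length(mates)
    }
    bbest <- Inf
    for (cl in ids) {
      if (cl == own) next
      members <- which(labels == cl)
      tot <- 0
      for (j in members) tot <- tot + D[i, j]
      m <- tot / length(members)
      if (m < bbest) {
        bbest <- m
        neighbor[i] <- cl
      }
    }
    b[i] <- bbest
    s[i] <- if (is.na(a[i])) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  list(a = a, b = b, s = s, neighbor = neighbor, asw = mean(s))
}

# Pair-enumeration adjusted Rand index: count agreeing pairs explicitly.
oracle_ari <- function(p, t) {
  n <- length(p)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_p <- p[i] == p[j]
      same_t <- t[i] == t[j]
      if (same_p && same_t) n11 <- n11 + 1
      else if (!same_p && !same_t) n00 <- n00 + 1
      else if (same_p) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  denom <- ((n11 + n10) + (n11 + n01)) / 2 - expected
  if (denom == 0) return(1)
  (n11 - expected) / denom
}

# Direct computation of normalized entropy: per predicted cluster, the
# truth-composition entropy over log(K).
oracle_entropy <- function(p, t) {
  K <- length(unique(t))
  total <- 0
  for (cl in unique(p)) {
    tt <- t[p == cl]
    e <- 0
    for (cls in unique(tt)) {
      pr <- sum(tt == cls) / length(tt)
      e <- e - pr * log(pr)
    }
    total <- total + length(tt) / length(p) * e / log(K)
  }
  total
}

# Random test instance: n points in 2-5 dims, labels guaranteeing >= 2
# non-empty clusters.
random_instance <- function(n, k, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * sample(2:5, 1)), nrow = n)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  list(X = X, D = euclidean_distances(X), labels = labels)
}

# Three well-separated Gaussian blobs in 2D.
make_blobs <- function(n_per = 20, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(c)
    cbind(rnorm(n_per, centers[c, 1], sd), rnorm(n_per, centers[c, 2], sd))))
  rownames(X) <- paste0("S", seq_len(3 * n_per))
  list(X = X, truth = rep(1:3, each = n_per))
}
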