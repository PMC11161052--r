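test_that("ARI closed forms: identity, relabeling, symmetry", {
  t <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(t, t), 1)
  relab <- c("b", "b", "a", "a", "c", "c")
  expect_equal(adjusted_rand_index(relab, t), 1)
  p <- c(1, 2, 1, 2, 3, 3)
  expect_equal(adjusted_rand_index(p, t), adjusted_rand_index(t, p))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI matches the pair-enumeration oracle on the 6-point example", {
  # contingency table [[2,1],[1,2]]
  p <- c(1, 1, 1, 2, 2, 2)
  t <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(p, t), oracle_ari(p, t), tolerance = 1e-14)
})

test_that("ARI matches the oracle and mclust on random partitions", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(8:25, 1)
    p <- sample.int(4, n, replace = TRUE)
    t <- sample.int(3, n, replace = TRUE)
    a <- adjusted_rand_index(p, t)
    expect_equal(a, oracle_ari(p, t), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(a, mclust::adjustedRandIndex(p, t), tolerance = 1e-12)
  }
})

test_that("entropy closed forms: purity, saturation, self-comparison", {
  t <- rep(1:3, each = 4)
  expect_equal(cluster_entropy(t, t), 0)
  # one predicted cluster holding equal counts of all K truth labels
  p_mixed <- rep(1, 12)
  expect_equal(cluster_entropy(p_mixed, t), 1, tolerance = 1e-12)
  expect_error(cluster_entropy(t, rep(1, 12)), "single truth class")
})

test_that("entropy matches the direct-formula oracle and is relabel-invariant", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(9:30, 1)
    p <- sample.int(3, n, replace = TRUE)
    t <- sample.int(3, n, replace = TRUE)
    e <- cluster_entropy(p, t)
    expect_equal(e, oracle_entropy(p, t), tolerance = 1e-12)
    expect_gte(e, 0)
    expect_lte(e, 1 + 1e-12)
    # relabeling predicted clusters changes nothing
    expect_equal(cluster_entropy(c("x", "y", "z")[p], t), e)
  }
})

test_that("entropy normalizer makes the log base cancel", {
  p <- c(1, 1, 2, 2, 2, 3)
  t <- c(1, 2, 1, 2, 3, 3)
  K <- 3
  base2 <- 0
  for (cl in unique(p)) {
    tt <- t[p == cl]
    pr <- table(tt) / length(tt)
    base2 <- base2 + length(tt) / length(p) *
      (-sum(pr * log2(pr)) / log2(K))
  }
  expect_equal(cluster_entropy(p, t), base2, tolerance = 1e-12)
})

test_that("WSS closed forms and the pairwise-distance identity", {
  X <- rbind(c(0, 0), c(2, 0))
  expect_equal(wss(X, c(1, 1)), 2)
  expect_equal(wss(X, c(1, 2)), 0)   # all singletons

  set.seed(5)
  Xr <- matrix(rnorm(40), 10, 4)
  lab <- sample.int(3, 10, replace = TRUE)
  # per cluster: sum ||x - mu||^2 = sum_{i<j} ||x_i - x_j||^2 / m
  byhand <- 0
  for (cl in unique(lab)) {
    xs <- Xr[lab == cl, , drop = FALSE]
    m <- nrow(xs)
    if (m == 1) next
    d2 <- as.matrix(stats::dist(xs))^2
    byhand <- byhand + sum(d2[upper.tri(d2)]) / m
  }
  expect_equal(wss(Xr, lab), byhand, tolerance = 1e-10)
})

test_that("NWSS self-normalizes to 1 and penalizes wrong labels on blobs", {
  b <- make_blobs(n_per = 10, seed = 3)
  expect_equal(normalized_wss(b$X, b$truth, b$truth), 1)
  set.seed(6)
  wrong <- sample(b$truth)
  expect_gt(normalized_wss(b$X, wrong, b$truth), 1)
  X1 <- rbind(c(0, 0), c(0, 0))
  expect_error(normalized_wss(X1, c(1, 2), c(1, 1)), "zero")
})

test_that("perfect classification is relabel-aware and counts over batches", {
  t <- rep(1:3, each = 5)
  relab <- c("c", "a", "b")[t]
  expect_true(perfect_classification(relab, t))
  swapped <- t
  swapped[c(1, 6)] <- swapped[c(6, 1)]
  expect_false(perfect_classification(swapped, t))
  batch <- list(relab, swapped, t, rep(1:3, times = 5))
  expect_equal(sum(vapply(batch, perfect_classification, logical(1), t = t)),
               2L)
})

test_that("perfect classification coincides with ARI == 1 on random cases", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:20, 1)
    p <- sample.int(3, n, replace = TRUE)
    t <- sample.int(3, n, replace = TRUE)
    expect_identical(perfect_classification(p, t),
                     abs(adjusted_rand_index(p, t) - 1) <= 1e-12)
  }
})

test_that("evaluate_clustering assembles all five indices", {
  b <- make_blobs(n_per = 8, seed = 9)
  D <- euclidean_distances(b$X)
  ev <- evaluate_clustering(b$truth, b$truth, X = b$X, D = D)
  expect_equal(ev$ari, 1)
  expect_equal(ev$entropy, 0)
  expect_equal(ev$nwss, 1)
  expect_true(ev$perfect)
  expect_equal(ev$asw, mean_silhouette(D, b$truth))
  ev2 <- evaluate_clustering(b$truth, b$truth)
  expect_true(is.na(ev2$asw) && is.na(ev2$nwss))
})
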