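test_that("a labeling with all non-negative silhouettes is a fixed point", {
  b <- make_blobs(n_per = 10, seed = 2)
  D <- euclidean_distances(b$X)
  st <- sillyputty_step(D, b$truth)
  expect_null(st$moved)
  expect_equal(st$labels, b$truth)
})

test_that("the step moves the oracle's argmin sample to its b-attaining cluster", {
  D <- euclidean_distances(cbind(x = c(0, 1, 10, 11)))
  labels <- c("A", "B", "B", "A")
  o <- oracle_silhouette(D, labels)
  # ties at the minimum (samples 1 and 4): lowest index wins
  expect_equal(o$s[1], min(o$s))
  expect_equal(o$s[4], min(o$s))
  st <- sillyputty_step(D, labels)
  expect_equal(st$moved, 1L)
  expect_equal(st$from, "A")
  expect_equal(st$to, o$neighbor[1])
  expect_equal(st$labels, c("B", "B", "B", "A"))
  # the moved sample's new cohesion equals its former separation-side mean
  o2 <- oracle_silhouette(D, st$labels)
  expect_equal(o2$a[1], o$b[1])
})

test_that("a perfect initialization converges in zero iterations", {
  b <- make_blobs(seed = 5)
  D <- euclidean_distances(b$X)
  res <- run_sillyputty(D, b$truth)
  expect_equal(res$termination, "converged")
  expect_equal(res$n_iterations, 0L)
  expect_equal(unname(res$labels), b$truth)
  expect_equal(nrow(res$trace), 0L)
})

test_that("random initializations on separated blobs recover the truth", {
  b <- make_blobs(n_per = 20, seed = 7)
  D <- euclidean_distances(b$X)
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    init <- sample.int(3, 60, replace = TRUE)
    init[1:3] <- 1:3
    res <- run_sillyputty(D, init)
    if (res$termination == "converged" &&
        isTRUE(perfect_classification(res$labels, b$truth)))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("result contracts hold: trace length, converged minimum, fixed point", {
  b <- make_blobs(n_per = 15, sd = 2, seed = 11)
  D <- euclidean_distances(b$X)
  set.seed(42)
  res <- run_sillyputty(D, sample.int(3, 45, replace = TRUE))
  expect_equal(nrow(res$trace), res$n_iterations)
  expect_true(res$termination %in% c("converged", "max_iter", "cycle_detected"))
  if (res$termination == "converged") {
    expect_gte(min(res$profile$sil_width), 0)
    again <- sillyputty_step(D, unname(res$labels))
    expect_null(again$moved)
  }
})

test_that("the iteration cap truncates a long refinement after one move", {
  b <- make_blobs(n_per = 15, seed = 13)
  D <- euclidean_distances(b$X)
  set.seed(3)
  init <- sample.int(3, 45, replace = TRUE)
  res <- run_sillyputty(D, init, sillyputty_config(max_iter = 1L,
                                                   loop_window = 1L))
  expect_equal(res$termination, "max_iter")
  expect_equal(res$n_iterations, 1L)
})

test_that("the moved sample's own silhouette strictly increases", {
  for (seed in 1:10) {
    inst <- random_instance(15, 3, seed + 50)
    st <- sillyputty_step(inst$D, inst$labels)
    if (is.null(st$moved)) next
    before <- oracle_silhouette(inst$D, inst$labels)
    after <- oracle_silhouette(inst$D, st$labels)
    expect_gt(after$s[st$moved], before$s[st$moved])
  }
})

test_that("random-start driver is deterministic and beats the truth ASW on blobs", {
  b <- make_blobs(n_per = 12, seed = 21)
  D <- euclidean_distances(b$X)
  cfg <- sillyputty_config(n_starts = 20, seed = 77)
  r1 <- sillyputty_random(D, 3, cfg)
  r2 <- sillyputty_random(D, 3, cfg)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$asw, r2$asw)
  expect_identical(r1$start, r2$start)
  truth_asw <- mean_silhouette(D, b$truth)
  expect_gte(r1$asw, truth_asw - 1e-9)
})

test_that("random-start driver validates its inputs", {
  D <- euclidean_distances(cbind(c(0, 1, 2)))
  expect_error(sillyputty_random(D, 5), "more clusters")
  expect_error(sillyputty_random(D, 1), "at least 2")
})

test_that("every random start has k non-empty clusters", {
  for (seed in 1:20) {
    set.seed(seed)
    init <- random_partition(10, 4)
    expect_setequal(unique(init), 1:4)
  }
})

test_that("label trajectories are invariant under distance rescaling", {
  b <- make_blobs(n_per = 10, sd = 2.5, seed = 31)
  D <- euclidean_distances(b$X)
  set.seed(8)
  init <- sample.int(3, 30, replace = TRUE)
  r1 <- run_sillyputty(D, init)
  for (c in c(0.5, 1000)) {
    rc <- run_sillyputty(validate_distance_matrix(unclass(D) * c), init)
    expect_equal(rc$trace$sample, r1$trace$sample)
    expect_equal(rc$trace$to, r1$trace$to)
    expect_equal(unname(rc$labels), unname(r1$labels))
    expect_equal(rc$termination, r1$termination)
  }
})

test_that("permuting samples and labels together permutes the clustering", {
  inst <- random_instance(18, 3, seed = 73)
  set.seed(9)
  init <- sample.int(3, 18, replace = TRUE)
  init[1:3] <- 1:3
  r1 <- run_sillyputty(inst$D, init)
  perm <- sample.int(18)
  Dp <- validate_distance_matrix(unclass(inst$D)[perm, perm])
  rp <- run_sillyputty(Dp, init[perm])
  expect_equal(unname(rp$labels), unname(r1$labels)[perm])
})

test_that("warm start repairs a deliberately swapped pair within two moves", {
  b <- make_blobs(n_per = 10, seed = 41)
  D <- euclidean_distances(b$X)
  init <- b$truth
  init[1] <- 2
  init[11] <- 1
  res <- sillyputty_warm(D, init)
  expect_lte(res$n_iterations, 2L)
  expect_true(perfect_classification(res$labels, b$truth))
  expect_true(res$warm_start)
})

test_that("warm start from k-means on overlapping blobs rarely hurts the ASW", {
  better <- 0L
  for (seed in 1:10) {
    b <- make_blobs(n_per = 15, sd = 3.5, seed = seed + 60)
    D <- euclidean_distances(b$X)
    set.seed(seed)
    km <- stats::kmeans(b$X, centers = 3, nstart = 2)$cluster
    res <- sillyputty_warm(D, km, sillyputty_config())
    if (res$asw >= mean_silhouette(D, km) - 1e-12) better <- better + 1L
  }
  expect_gte(better, 9L)
})
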