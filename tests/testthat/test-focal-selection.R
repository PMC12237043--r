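test_that("cosine similarity matches hand values and handles degenerate input", {
  expect_equal(cosine_similarity(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(round(cosine_similarity(c(1, 1), c(1, 0)), 5), 0.70711)
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)  # zero-norm convention
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("cluster assignment picks the most similar centroid, ties to lower index", {
  X <- diag(3)  # three orthogonal samples
  expect_equal(assign_clusters(X, matrix(c(1, 1, 1), nrow = 1)), rep(1L, 3))
  cents <- diag(3)
  expect_equal(assign_clusters(matrix(c(0, 0, 1), 1), cents), 3L)
  # equidistant from centroids 1 and 2
  expect_equal(assign_clusters(matrix(c(1, 1, 0), 1), cents[1:2, ]), 1L)
})

test_that("centroid update is the within-cluster mean with empty-cluster repair", {
  X <- rbind(c(0, 0), c(2, 2))
  expect_equal(update_centroids(X, c(1L, 1L), 1)[1, ], c(1, 1))
  X2 <- rbind(c(5, 7))
  expect_equal(update_centroids(X2, 1L, 1)[1, ], c(5, 7))
  X3 <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(update_centroids(X3, rep(1L, 3), 1)[1, ], c(0, 1 / 3))
  # cluster 2 empty: re-seeded from the worst-fit sample, not left at zero
  rep2 <- update_centroids(X3, rep(1L, 3), 2)
  expect_false(all(rep2[2, ] == 0))
  expect_true(any(apply(X3, 1, function(r) all(r == rep2[2, ]))))
})

test_that("spherical k-means is monotone, deterministic, and saturates at k = n", {
  set.seed(31)
  for (r in 1:10) {
    n <- sample(20:60, 1)
    d <- sample(2:6, 1)
    X <- matrix(rnorm(n * d), n, d)
    fs <- kmeans_cosine(X, k = sample(2:5, 1), seed = r)
    expect_true(all(diff(fs$objective) >= -1e-9))
  }
  X <- matrix(rnorm(8 * 3), 8, 3)
  fs_sat <- kmeans_cosine(X, k = 8, seed = 1)
  # every sample its own cluster: objective equals n (unit self-similarity)
  expect_equal(utils::tail(fs_sat$objective, 1), 8, tolerance = 1e-9)
  expect_equal(sort(unique(fs_sat$assignments)), 1:8)

  f1 <- kmeans_cosine(X, 3, seed = 5)
  f2 <- kmeans_cosine(X, 3, seed = 5)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$foci, f2$foci)
})

test_that("two antipodal groups are recovered exactly as the brute-force best split", {
  set.seed(12)
  base <- c(1, 0.5, 0.25)
  X <- rbind(
    t(replicate(5, base + rnorm(3, 0, 0.02))),
    t(replicate(5, -base + rnorm(3, 0, 0.02))))
  fs <- kmeans_cosine(X, 2, seed = 4)
  oracle <- oracle_best_2partition(X)
  expect_equal(utils::tail(fs$objective, 1), oracle$objective,
               tolerance = 1e-6)
  groups <- split(seq_len(10), fs$assignments)
  expect_setequal(groups[[1]], which(oracle$assign == oracle$assign[groups[[1]][1]]))
})

test_that("focus selection matches an exhaustive within-cluster argmax", {
  set.seed(9)
  X <- matrix(rnorm(15 * 4), 15, 4)
  fs <- kmeans_cosine(X, 3, seed = 2)
  for (j in seq_len(3)) {
    members <- which(fs$assignments == j)
    sims <- vapply(members, function(i)
      cosine_similarity(X[i, ], fs$centroids[j, ]), numeric(1))
    expect_equal(fs$foci[j], members[which.max(sims)])
    expect_true(fs$foci[j] %in% members)
  }
  expect_equal(anyDuplicated(fs$foci), 0)

  # singleton cluster: the focus is forced
  Xs <- rbind(c(1, 0), c(0.99, 0.1), c(-1, 0))
  fss <- kmeans_cosine(Xs, 2, seed = 1)
  single <- which(tabulate(fss$assignments, 2) == 1)
  if (length(single) == 1) {
    expect_equal(fss$foci[single], which(fss$assignments == single))
  }
})

test_that("clustering structure is invariant to row permutation", {
  set.seed(77)
  X <- rbind(matrix(rnorm(12, 5), 4, 3), matrix(rnorm(12, -5), 4, 3))
  fs <- kmeans_cosine(X, 2, seed = 3)
  perm <- sample(8)
  fsp <- kmeans_cosine(X[perm, ], 2, seed = 3)
  # compare partitions canonically: sets of member-index sets
  canon <- function(assign, order_map = seq_along(assign)) {
    parts <- split(order_map, assign)
    parts <- lapply(parts, sort)
    parts[order(vapply(parts, min, numeric(1)))]
  }
  expect_equal(unname(canon(fs$assignments)),
               unname(canon(fsp$assignments, perm)))
})

test_that("default focus count follows round(sqrt(n/2))", {
  expect_equal(default_k(100000), 224L)
  expect_equal(default_k(50), 5L)
  expect_equal(default_k(2), 1L)
  expect_error(kmeans_cosine(matrix(1:4, 2), k = 3, seed = 1), "exceeds")
  expect_error(kmeans_cosine(matrix(1:4, 2), k = 0, seed = 1), ">= 1")
})
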