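test_that("kmeans degenerate cases follow closed forms", {
  x <- matrix(c(0, 0, 5, 5, 10, 0), 3, 2, byrow = TRUE)
  r <- kmeans_cluster(x, K = 3, seed = 1)
  expect_equal(sort(unique(r$labels)), 0:2)
  expect_equal(r$wcss, 0)
  r1 <- kmeans_cluster(x, K = 1, seed = 1)
  expect_equal(r1$centers[1, ], colMeans(x))
  expect_error(kmeans_cluster(x, K = 4), "exceeds")
})

test_that("kmeans recovers planted gaussians and matches stats::kmeans", {
  pg <- planted_gaussians(n_per = 100, F = 2, sep = 10, sd = 1)
  r <- kmeans_cluster(pg$x, K = 3, seed = 5)
  mp <- map_clusters_to_classes(r$labels, pg$labels)
  expect_equal(mean(attr(mp, "class_labels") == pg$labels), 1.0)
  # independent route: stats::kmeans on the same data
  ref <- stats::kmeans(pg$x, centers = 3, nstart = 10)
  agree <- map_clusters_to_classes(r$labels, ref$cluster - 1L)
  expect_equal(mean(attr(agree, "class_labels") == ref$cluster - 1L), 1.0)
})

test_that("kmeans is deterministic under a fixed seed", {
  pg <- planted_gaussians(n_per = 40, F = 3, sep = 6)
  a <- kmeans_cluster(pg$x, 3, seed = 9)
  b <- kmeans_cluster(pg$x, 3, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("fcm memberships are a partition of unity and converge", {
  pg <- planted_gaussians(n_per = 50, F = 2, sep = 10)
  r <- fcm_cluster(pg$x, K = 3, seed = 2)
  expect_equal(unname(rowSums(r$membership)), rep(1, 150), tolerance = 1e-9)
  mp <- map_clusters_to_classes(r$labels, pg$labels)
  expect_equal(mean(attr(mp, "class_labels") == pg$labels), 1.0)
  expect_error(fcm_cluster(pg$x, K = 3, m = 1), "m must be > 1")
})

test_that("two points collapse to their own centres with crisp membership", {
  x <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  r <- fcm_cluster(x, K = 2, seed = 1, tol = 1e-12)
  ord <- order(r$centers[, 1])
  expect_equal(r$centers[ord, ], x, tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(all(apply(r$membership, 1, max) > 0.999))
})

test_that("fcm agrees with kmeans on separated data, and with e1071", {
  pg <- planted_gaussians(n_per = 100, F = 2, sep = 10, seed = 4)
  km <- kmeans_cluster(pg$x, 3, seed = 3)
  fc <- fcm_cluster(pg$x, 3, m = 2, seed = 3)
  mp <- map_clusters_to_classes(fc$labels, km$labels)
  expect_gte(mean(attr(mp, "class_labels") == km$labels), 0.99)
  # near-crisp limit m -> 1+ reproduces the hard partition
  fc1 <- fcm_cluster(pg$x, 3, m = 1.05, seed = 3)
  mp1 <- map_clusters_to_classes(fc1$labels, km$labels)
  expect_gte(mean(attr(mp1, "class_labels") == km$labels), 0.99)
  skip_if_not_installed("e1071")
  ref <- e1071::cmeans(pg$x, centers = 3, m = 2)
  mpe <- map_clusters_to_classes(fc$labels, ref$cluster - 1L)
  expect_gte(mean(attr(mpe, "class_labels") == ref$cluster - 1L), 0.99)
})

test_that("dp state matches the brute-force oracle on a fixed 1-D set", {
  x <- matrix(c(0, 0.1, 0.2, 0.25, 5, 5.1, 5.15, 9), ncol = 1)
  r <- dp_cluster(x, K = 2, dc_percentile = 0.2, seed = 1)
  st <- r$dp_state
  o <- dp_oracle(x, st$dc)
  expect_identical(st$rho, o$rho)
  expect_equal(st$delta, o$delta, tolerance = 1e-12)
  expect_equal(st$gamma, o$gamma, tolerance = 1e-12)
  # the global density maximum takes the largest pairwise distance
  top <- which(o$rho == max(o$rho))[1]
  expect_equal(st$delta[top], max(abs(outer(x[, 1], x[, 1], `-`))[top, ]))
})

test_that("dp equals the oracle exactly over many random 2-D sets", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(20:300, 1)
    if (rep <= 3) n <- sample(400:500, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    if (rep %% 2 == 0) X <- round(X, 1)   # force density ties
    r <- dp_cluster(X, K = 3, dc_percentile = 0.02, seed = rep)
    o <- dp_oracle(X, r$dp_state$dc)
    expect_identical(r$dp_state$rho, o$rho)
    expect_equal(r$dp_state$delta, o$delta, tolerance = 1e-12)
    expect_equal(r$dp_state$gamma, o$gamma, tolerance = 1e-12)
  }
})

test_that("dp recovers planted gaussians with centres near the truth", {
  pg <- planted_gaussians(n_per = 100, F = 2, sep = 10, sd = 1, seed = 23)
  r <- dp_cluster(pg$x, K = 3, seed = 2)
  # top-3 gamma points each lie within 2 SD of a distinct planted centre
  d2c <- specmite:::squared_dist_to_centers(r$centers, pg$centers)
  nearest <- apply(d2c, 1, which.min)
  expect_identical(sort(nearest), 1:3)
  expect_true(all(sqrt(apply(d2c, 1, min)) < 2))
  mp <- map_clusters_to_classes(r$labels, pg$labels)
  expect_equal(mean(attr(mp, "class_labels") == pg$labels), 1.0)
})

test_that("dp subsampling assigns out-of-sample pixels consistently", {
  pg <- planted_gaussians(n_per = 300, F = 2, sep = 12, seed = 31)
  r <- dp_cluster(pg$x, K = 3, max_fit_points = 200L, seed = 5)
  mp <- map_clusters_to_classes(r$labels, pg$labels)
  expect_gte(mean(attr(mp, "class_labels") == pg$labels), 0.999)
  expect_identical(length(r$dp_state$fit_idx), 200L)
})

test_that("identical points collapse to one cluster with a warning", {
  x <- matrix(1, 10, 2)
  expect_warning(r <- dp_cluster(x, K = 3, seed = 1), "identical")
  expect_identical(unique(r$labels), 0L)
})

test_that("clusterers are invariant to feature permutation and shifts", {
  pg <- planted_gaussians(n_per = 60, F = 3, sep = 10, seed = 41)
  perm <- c(3, 1, 2)
  shift <- matrix(5, nrow(pg$x), 3)
  for (fn in list(
    function(x, s) kmeans_cluster(x, 3, seed = s)$labels,
    function(x, s) fcm_cluster(x, 3, seed = s)$labels,
    function(x, s) dp_cluster(x, 3, seed = s)$labels)) {
    base <- fn(pg$x, 7)
    expect_identical(fn(pg$x[, perm], 7), base)
    expect_identical(fn(pg$x + shift, 7), base)
  }
})

test_that("cluster-class mapping maximizes agreement (brute force oracle)", {
  # permuted perfect clustering maps back to OA 1
  ref <- rep(0:2, times = c(10, 20, 30))
  perm_lab <- c(2L, 0L, 1L)[ref + 1L]
  mp <- map_clusters_to_classes(perm_lab, ref)
  expect_equal(mean(attr(mp, "class_labels") == ref), 1.0)

  # random overlap tables against exhaustive 6-permutation search
  set.seed(19)
  for (rep in 1:20) {
    cl <- sample(0:2, 60, replace = TRUE)
    rf <- sample(0:2, 60, replace = TRUE)
    mp <- map_clusters_to_classes(cl, rf)
    got <- sum(attr(mp, "class_labels") == rf)
    best <- max(sapply(specmite:::all_permutations(3), function(p) {
      sum((p - 1L)[cl + 1L] == rf)
    }))
    expect_identical(got, best)
  }
})

test_that("single cluster maps to the modal class; empty overlap warns", {
  ref <- rep(c(0L, 1L), times = c(3, 7))
  mp <- map_clusters_to_classes(rep(0L, 10), ref, K = 1L, n_classes = 2L)
  expect_identical(as.integer(mp), 1L)
  ref2 <- c(rep(0L, 5), rep(-1L, 5))
  cl2 <- c(rep(0L, 5), rep(1L, 5))   # cluster 1 overlaps nothing labeled
  expect_warning(mp2 <- map_clusters_to_classes(cl2, ref2, K = 2L,
                                                n_classes = 3L),
                 "modal")
  expect_identical(as.integer(mp2)[2], 0L)
})
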