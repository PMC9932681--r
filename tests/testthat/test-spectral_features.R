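test_that("pca recovers closed-form eigenstructure and ranks variance", {
  # construct pixels whose sample covariance is exactly [[2,1],[1,2]]:
  # whiten iid draws, then colour by the Cholesky factor
  set.seed(4)
  n <- 50
  z <- matrix(rnorm(n * 2), n, 2)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(stats::cov(z)))
  x <- z %*% chol(matrix(c(2, 1, 1, 2), 2))
  x <- x / 10 + 0.5   # common rescale keeps ratios, reflectance in [0,1]
  cube <- tiny_cube(x, c(500, 600), H = 5L, W = 10L)
  fs <- pca_features(cube, n_components = 2L)
  ratio <- attr(fs, "explained_variance_ratio")
  expect_equal(ratio, c(0.75, 0.25), tolerance = 1e-10)
  # components orthonormal
  rot <- attr(fs, "loadings")
  expect_equal(t(rot) %*% rot, diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  expect_true(all(apply(rot, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("rank-1 data puts all variance on the first component", {
  t <- seq(0, 1, length.out = 24)
  x <- outer(t, c(0.2, 0.4, 0.6)) + 0.1
  cube <- tiny_cube(x, c(500, 600, 700), H = 4L, W = 6L)
  fs <- pca_features(cube, n_components = 3L)
  expect_equal(attr(fs, "explained_variance_ratio")[1], 1, tolerance = 1e-12)
  expect_error(pca_features(cube, n_components = 4L), "exceeds band count")
})

test_that("pca ratios are non-increasing and bounded for noisy scenes", {
  sc <- small_scene(seed = 8, n = 16L, blob_scale = 3)
  fs <- pca_features(sc$cube)
  r <- attr(fs, "explained_variance_ratio")
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= 0) && sum(r) <= 1 + 1e-12)
})

test_that("lle preserves the ordering of a planted 1-D arc", {
  t <- seq(0, 1, length.out = 60)
  x <- sapply(1:10, function(b) 0.4 + 0.25 * sin(2 * t + b / 3))
  cube <- tiny_cube(x, seq(500, 950, length.out = 10), H = 6L, W = 10L)
  fs <- lle_features(cube, n_neighbors = 8L, n_components = 1L)
  emb <- matrix(fs$data, 60, 1)[, 1]   # column-major pixel order
  expect_equal(abs(stats::cor(emb, t, method = "spearman")), 1,
               tolerance = 1e-12)
})

test_that("lle reconstruction weights sum to one and contract errors", {
  set.seed(9)
  X <- matrix(runif(40 * 5), 40, 5)
  W <- specmite:::lle_weights_to(X, X, 6L, 1e-3, exclude_self = TRUE)$w
  expect_equal(unname(rowSums(W)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(abs(diag(W)) == 0))
})

test_that("lle rejects infeasible neighbourhood sizes", {
  cube <- tiny_cube(matrix(runif(20), 4, 5), seq(500, 900, length.out = 5),
                    H = 2L, W = 2L)
  expect_error(lle_features(cube, n_neighbors = 4L), "must be <")
  expect_error(lle_features(cube, n_neighbors = 3L, n_components = 4L),
               "n_components")
})

test_that("spectral sensitivity matches its defining ratio and signs", {
  p <- spectral_sensitivity(c(0.3, 0.1, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(p$S, c(0.5, -0.5, 0))
  expect_error(spectral_sensitivity(c(0.3), c(0)), "must be > 0")
  expect_error(spectral_sensitivity(c(0.3, 0.1), c(0.2)), "equal length")
})

test_that("spectral sensitivity is invariant to common scaling", {
  set.seed(12)
  sh <- runif(45, 0.1, 0.6); ss <- runif(45, 0.1, 0.6)
  s1 <- spectral_sensitivity(ss, sh)$S
  for (c in c(0.5, 2, 7.3)) {
    expect_equal(spectral_sensitivity(c * ss, c * sh)$S, s1,
                 tolerance = 1e-12)
  }
})

test_that("greedy band selection obeys |S| order and separation", {
  prof <- spectral_sensitivity(c(0.38, 0.36, 0.22, 0.34), rep(0.2, 4),
                               wavelengths = c(500, 510, 600, 700))
  # S = 0.9, 0.8, 0.1, 0.7: greedy takes 500, skips 510 (< 50 nm), takes 700
  sel <- select_sensitive_bands(prof, k = 2L, min_separation = 50)
  expect_identical(as.integer(sel), c(1L, 4L))
  # min_separation 0 reduces to top-k by |S|
  sel0 <- select_sensitive_bands(prof, k = 2L, min_separation = 0)
  expect_identical(as.integer(sel0), c(1L, 2L))
  # k = 1 is the argmax
  expect_identical(as.integer(select_sensitive_bands(prof, k = 1L,
                                                     min_separation = 50)),
                   1L)
  expect_error(select_sensitive_bands(prof, k = 4L, min_separation = 150),
               "maximum feasible")
})

test_that("greedy selection equals an exhaustive re-application of its rule", {
  # independent oracle: re-derive the greedy choice by scanning the full
  # |S| ranking at every step and checking all pairwise separations
  greedy_oracle <- function(S, wl, k, sep) {
    ord <- order(-abs(S), wl)
    kept <- integer(0)
    for (b in ord) {
      if (length(kept) == k) break
      if (all(abs(wl[b] - wl[kept]) >= sep) || !length(kept))
        kept <- c(kept, b)
    }
    sort(kept)
  }
  set.seed(21)
  for (rep in 1:25) {
    B <- sample(5:12, 1)
    wl <- sort(runif(B, 450, 900))
    S <- runif(B, -1, 1)
    sep <- sample(c(0, 30, 80, 150), 1)
    prof <- spectral_sensitivity(0.2 * (1 + S), rep(0.2, B), wl)
    k <- sample(1:3, 1)
    got <- tryCatch(select_sensitive_bands(prof, k = k, min_separation = sep),
                    error = function(e) NULL)
    want <- greedy_oracle(S, wl, k, sep)
    if (is.null(got)) {
      expect_lt(length(want), k)
    } else {
      expect_identical(as.integer(got), want)
      # pairwise separation honoured
      if (length(got) > 1)
        expect_true(min(dist(wl[got])) >= sep)
    }
  }
})

test_that("asp partition recovers planted correlation blocks exactly", {
  wl <- seq(450, 900, length.out = 8)
  cube <- planted_block_cube(blocks = list(1:4, 5:8), wavelengths = wl)
  sub <- asp_band_partition(cube, theta = 0.9)
  expect_identical(sub$starts, c(1L, 5L))

  cube3 <- planted_block_cube(blocks = list(1:3, 4:5, 6:8),
                              wavelengths = wl, seed = 9)
  sub3 <- asp_band_partition(cube3, theta = 0.9)
  expect_identical(sub3$starts, c(1L, 4L, 6L))
})

test_that("identical bands form a single subspace, random bands many", {
  wl <- seq(450, 900, length.out = 6)
  set.seed(5)
  sig <- runif(40, 0.2, 0.8)
  x <- matrix(rep(sig, 6), 40, 6)
  cube <- tiny_cube(x, wl, H = 4L, W = 10L)
  sub <- asp_band_partition(cube, theta = 0.9)
  expect_identical(sub$starts, 1L)

  # independent random bands at theta = 0.5: brute-force recount of the rule
  xr <- matrix(runif(6 * 200), 200, 6)
  cr <- tiny_cube(xr, wl, H = 10L, W = 20L)
  subr <- asp_band_partition(cr, theta = 0.5)
  r <- subr$adjacent_corr
  is_min <- vapply(seq_along(r), function(b) {
    (b == 1 || r[b] <= r[b - 1]) && (b == length(r) || r[b] <= r[b + 1])
  }, logical(1))
  expect_identical(length(subr$starts), 1L + sum(is_min & r < 0.5))
})

test_that("asp cuts are invariant to pixel order", {
  wl <- seq(450, 900, length.out = 8)
  cube <- planted_block_cube(blocks = list(1:4, 5:8), wavelengths = wl)
  x <- matrix(cube$data, 60, 8)
  set.seed(3)
  perm <- sample(60)
  cube_p <- tiny_cube(x[perm, ], wl, H = 6L, W = 10L)
  expect_identical(asp_band_partition(cube, theta = 0.9)$starts,
                   asp_band_partition(cube_p, theta = 0.9)$starts)
})

test_that("representative bands are subspace medoids (brute force)", {
  wl <- seq(450, 900, length.out = 9)
  cube <- planted_block_cube(blocks = list(1:3, 4:6, 7:9), wavelengths = wl,
                             seed = 13)
  sub <- asp_band_partition(cube, theta = 0.9)
  expect_identical(length(sub$starts), 3L)
  reps <- select_representative_bands(sub, cube, k = 3L)
  cm <- sub$corr
  for (g in split(1:9, sub$membership)) {
    score <- vapply(g, function(b) sum(abs(cm[b, setdiff(g, b)])), numeric(1))
    expect_true(any(reps %in% g[score == max(score)]))
  }
  expect_identical(findInterval(as.integer(reps), sub$starts), 1:3)
})

test_that("constant-band subspaces break medoid ties toward the middle", {
  wl <- seq(450, 900, length.out = 5)
  x <- matrix(rep(runif(30, 0.2, 0.8), 5), 30, 5)
  cube <- tiny_cube(x, wl, H = 5L, W = 6L)
  sub <- suppressWarnings(asp_band_partition(cube, theta = 0.9))
  reps <- select_representative_bands(sub, cube, k = 1L)
  expect_identical(as.integer(reps), 3L)   # middle of 1..5
})
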