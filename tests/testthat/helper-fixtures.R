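# Small in-code fixtures shared across test files.

# tiny cube with prescribed per-pixel spectra: spectra is an N x B matrix,
# laid out into an H x W grid column-major
tiny_cube <- function(spectra, wavelengths, H = NULL, W = NULL) {
  N <- nrow(spectra)
  if (is.null(H)) { H <- 1L; W <- N } else if (is.null(W)) W <- N / H
  reflectance_cube(array(spectra, dim = c(H, W, ncol(spectra))), wavelengths)
}

# cube whose bands are copies of planted signals (for band-clustering tests):
# blocks is a list of integer vectors of band indices; each block shares one
# random signal, plus tiny jitter so correlations are well defined
planted_block_cube <- function(n_pixels = 60, blocks, wavelengths,
                               jitter = 1e-3, seed = 7) {
  set.seed(seed)
  B <- length(wavelengths)
  x <- matrix(0, n_pixels, B)
  for (blk in blocks) {
    sig <- runif(n_pixels, 0.2, 0.8)
    for (b in blk) x[, b] <- sig + rnorm(n_pixels, sd = jitter)
  }
  x <- pmin(pmax(x, 0), 1)
  tiny_cube(x, wavelengths, H = 6L, W = n_pixels / 6L)
}

# three well-separated spherical Gaussians in F dims; returns features and
# planted labels (0-based)
planted_gaussians <- function(n_per = 100, F = 2, sep = 10, sd = 1,
                              seed = 11) {
  set.seed(seed)
  centers <- matrix(0, 3, F)
  centers[2, 1] <- sep * sd
  centers[3, seq_len(min(2, F))] <- c(sep * sd / 2, sep * sd * 0.866)[
    seq_len(min(2, F))]
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * F, sd = sd), n_per, F), 2, centers[k, ], `+`)))
  list(x = x, labels = rep(0:2, each = n_per), centers = centers)
}

# brute-force density-peak oracle: explicit per-point loops over the printed
# rules (cutoff density, strictly-denser delta with index tie-break)
dp_oracle <- function(X, dc) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in 1:n) d[i, ] <- sqrt(colSums((t(X) - X[i, ])^2))
  rho <- integer(n)
  for (i in 1:n) rho[i] <- sum(d[i, -i] < dc)
  denser <- function(i) {
    which(rho > rho[i] | (rho == rho[i] & seq_len(n) < i))
  }
  delta <- numeric(n); parent <- integer(n)
  for (i in 1:n) {
    hs <- denser(i)
    if (!length(hs)) {
      delta[i] <- max(d[i, ])
      parent[i] <- 0L
    } else {
      j <- hs[which.min(d[i, hs])]
      delta[i] <- d[i, j]
      parent[i] <- j
    }
  }
  list(rho = rho, delta = delta, gamma = rho * delta, parent = parent)
}

# default small synthetic scene for pipeline tests
small_scene <- function(seed = 3, noise_sd = 0.01, mixing_width = 1L,
                        n = 48L, blob_scale = 6) {
  generate_scene(scene_spec(height = n, width = n, blob_scale = blob_scale,
                            noise_sd = noise_sd, mixing_width = mixing_width,
                            seed = seed))
}
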