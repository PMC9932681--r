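## Spectral feature construction: four ways of compressing the band axis of a
## reflectance cube into the low-dimensional space fed to the clusterers.
##   pca_features            — linear feature extraction (covariance eigenbasis)
##   lle_features            — nonlinear manifold embedding
##   spectral_sensitivity    — (stressed - healthy)/healthy per band, and
##   select_sensitive_bands  — greedy |S|-ranked band picking with a minimum
##                             wavelength separation
##   asp_band_partition      — correlation-block subspace partition, and
##   select_representative_bands — one medoid band per subspace

# pixels of a cube as an N x B matrix (unmasked only); returns the matrix and
# the linear pixel indices it came from
cube_pixels <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  m <- if (is.null(mask)) cube$mask else (mask | cube$mask)
  keep <- which(!m)
  x <- matrix(cube$data, d[1] * d[2], d[3])[keep, , drop = FALSE]
  list(x = x, idx = keep, dims = d)
}

# rebuild an H x W x F array from per-pixel feature rows (NA where masked)
unflatten_features <- function(values, idx, dims_hw, n_feat) {
  out <- array(NA_real_, dim = c(dims_hw, n_feat))
  flat <- matrix(NA_real_, prod(dims_hw), n_feat)
  flat[idx, ] <- values
  array(flat, dim = c(dims_hw, n_feat))
}

#' Low-dimensional feature stack
#'
#' @param data numeric H x W x F array (NA on masked pixels).
#' @param feature_names length-F character vector.
#' @param method one of `"pca"`, `"lle"`, `"ss"`, `"bc"`, `"bands"`.
#' @return object of class `feature_stack`.
#' @export
feature_stack <- function(data, feature_names, method) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(feature_names))
  structure(list(data = data, feature_names = feature_names, method = method),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("feature_stack (%s): %d x %d pixels, %d feature(s): %s\n",
              x$method, d[1], d[2], d[3],
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Principal-component features
#'
#' Projects unmasked pixel spectra onto the leading eigenvectors of their
#' covariance matrix. The sign of each component is fixed so its
#' largest-magnitude loading is positive. The default of four components
#' retains essentially all variance of typical 45-band canopy scenes.
#'
#' @param cube a [reflectance_cube()].
#' @param mask optional extra logical H x W exclusion mask.
#' @param n_components number of components (<= B).
#' @return a [feature_stack()] with attribute `"explained_variance_ratio"`
#'   (length `n_components`, non-increasing, sums to <= 1) and `"loadings"`
#'   (B x F).
#' @export
pca_features <- function(cube, mask = NULL, n_components = 4L) {
  px <- cube_pixels(cube, mask)
  B <- ncol(px$x)
  if (n_components > B) stop("n_components (", n_components,
                             ") exceeds band count (", B, ")")
  if (nrow(px$x) < n_components) stop("fewer unmasked pixels than components")
  pc <- stats::prcomp(px$x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- scale(px$x, center = pc$center, scale = FALSE) %*% rot
  ev <- pc$sdev^2
  ratio <- ev[seq_len(n_components)] / sum(ev)
  fs <- feature_stack(
    unflatten_features(scores, px$idx, px$dims[1:2], n_components),
    paste0("PC", seq_len(n_components)), "pca")
  attr(fs, "explained_variance_ratio") <- ratio
  attr(fs, "loadings") <- rot
  fs
}

#' Locally linear embedding features
#'
#' Standard LLE: k-nearest-neighbour reconstruction weights (rows sum to 1,
#' local Gram matrix regularized by `reg * tr(G)/k`), then the bottom
#' non-trivial eigenvectors of (I-W)'(I-W). For scenes larger than
#' `max_fit_points` pixels the embedding is fitted on a seeded uniform
#' landmark subsample and remaining pixels are embedded through their
#' reconstruction weights onto the landmarks (the usual out-of-sample
#' extension); the dense eigenproblem stays tractable that way.
#'
#' @inheritParams pca_features
#' @param n_neighbors neighbourhood size (default 12).
#' @param n_components embedding dimension (<= n_neighbors).
#' @param reg Gram-matrix regularization factor (default 1e-3).
#' @param max_fit_points landmark budget for the eigenproblem.
#' @param seed RNG seed for the landmark subsample.
#' @return a [feature_stack()].
#' @export
lle_features <- function(cube, mask = NULL, n_neighbors = 12L,
                         n_components = 4L, reg = 1e-3,
                         max_fit_points = 2000L, seed = 1L) {
  px <- cube_pixels(cube, mask)
  N <- nrow(px$x)
  if (n_neighbors >= N)
    stop("n_neighbors (", n_neighbors, ") must be < number of pixels (", N, ")")
  if (n_components > n_neighbors)
    stop("n_components must be <= n_neighbors")
  if (N > max_fit_points) {
    land <- with_seed(seed, sample.int(N, max_fit_points))
    land <- sort(land)
  } else {
    land <- seq_len(N)
  }
  XL <- px$x[land, , drop = FALSE]
  Y <- lle_fit(XL, n_neighbors, n_components, reg)
  emb <- matrix(NA_real_, N, n_components)
  emb[land, ] <- Y
  rest <- setdiff(seq_len(N), land)
  if (length(rest)) {
    W <- lle_weights_to(px$x[rest, , drop = FALSE], XL, n_neighbors, reg)
    emb[rest, ] <- W$w %*% Y  # sparse rows realized as dense k-col products
  }
  feature_stack(unflatten_features(emb, px$idx, px$dims[1:2], n_components),
                paste0("LLE", seq_len(n_components)), "lle")
}

# reconstruction weights of each row of Xq onto its k nearest rows of Xref;
# returns dense N x nrow(Xref) weight matrix (zero off-neighbourhood)
lle_weights_to <- function(Xq, Xref, k, reg, exclude_self = FALSE) {
  n <- nrow(Xq); m <- nrow(Xref)
  w <- matrix(0, n, m)
  ref2 <- rowSums(Xref^2)
  for (i in seq_len(n)) {
    d2 <- ref2 - 2 * drop(Xref %*% Xq[i, ]) + sum(Xq[i, ]^2)
    if (exclude_self) d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    Z <- sweep(Xref[nb, , drop = FALSE], 2, Xq[i, ])
    G <- Z %*% t(Z)
    tr <- sum(diag(G))
    G <- G + diag(k) * (if (tr > 0) reg * tr / k else reg)
    wi <- solve(G, rep(1, k))
    w[i, nb] <- wi / sum(wi)
  }
  list(w = w)
}

# Euclidean minimum spanning tree (Prim); returns edge list (2-col matrix)
mst_edges <- function(d2) {
  n <- nrow(d2)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_d <- d2[, 1]
  best_from <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]
    edges[e, ] <- c(best_from[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & d2[, v] < best_d
    best_d[upd] <- d2[upd, v]
    best_from[upd] <- v
  }
  edges
}

lle_fit <- function(X, k, f, reg) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  nbrs <- lapply(seq_len(n), function(i) order(d2[i, ])[2:(k + 1L)])
  # kNN graphs of scenes with well-separated classes fall apart into
  # disconnected islands, leaving the embedding eigenproblem degenerate
  # (one arbitrary null vector per island); grafting the Euclidean minimum
  # spanning tree onto the neighbourhoods keeps the graph connected while
  # adding the fewest, shortest possible bridges.
  for (e in seq_len(nrow(me <- mst_edges(d2)))) {
    u <- me[e, 1]; v <- me[e, 2]
    nbrs[[u]] <- union(nbrs[[u]], v)
    nbrs[[v]] <- union(nbrs[[v]], u)
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    ki <- length(nb)
    Z <- sweep(X[nb, , drop = FALSE], 2, X[i, ])
    G <- Z %*% t(Z)
    tr <- sum(diag(G))
    G <- G + diag(ki) * (if (tr > 0) reg * tr / ki else reg)
    wi <- solve(G, rep(1, ki))
    W[i, nb] <- wi / sum(wi)
  }
  M <- diag(n) - W
  M <- t(M) %*% M
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  # bottom eigenvectors, discarding the trivial (constant) last one
  sel <- seq(n - 1L, n - f, by = -1L)
  Y <- e$vectors[, sel, drop = FALSE] * sqrt(n)
  for (j in seq_len(ncol(Y))) {
    i <- which.max(abs(Y[, j]))
    if (Y[i, j] < 0) Y[, j] <- -Y[, j]
  }
  Y
}

#' Spectral sensitivity profile
#'
#' Per-band relative reflectance difference between stressed and healthy
#' canopies, S_b = (Ss_b - Sh_b) / Sh_b. Large |S| marks wavelengths where
#' stress is easiest to see; the sign records whether stress raises (visible)
#' or lowers (near-infrared) reflectance.
#'
#' @param stressed_mean,healthy_mean length-B mean reflectance spectra;
#'   `healthy_mean` must be strictly positive.
#' @param wavelengths optional length-B wavelength vector (nm), kept for band
#'   selection.
#' @return object of class `sensitivity_profile` with fields `S`,
#'   `healthy_mean`, `stressed_mean`, `wavelengths`.
#' @export
spectral_sensitivity <- function(stressed_mean, healthy_mean,
                                 wavelengths = NULL) {
  if (length(stressed_mean) != length(healthy_mean))
    stop("spectra must have equal length")
  if (any(healthy_mean <= 0))
    stop("healthy_mean must be > 0 everywhere (division undefined)")
  structure(list(S = (stressed_mean - healthy_mean) / healthy_mean,
                 healthy_mean = healthy_mean, stressed_mean = stressed_mean,
                 wavelengths = wavelengths),
            class = "sensitivity_profile")
}

#' Greedy selection of stress-sensitive bands
#'
#' Bands are visited in decreasing |S| (ties broken toward the lower
#' wavelength); a band is taken unless it lies within `min_separation` nm of
#' one already taken. The two working constraints are thus high sensitivity
#' and a long inter-band interval.
#'
#' @param profile a [spectral_sensitivity()] with `wavelengths` set (or pass
#'   `wavelengths`).
#' @param k number of bands (default 7).
#' @param min_separation minimum pairwise wavelength distance in nm.
#' @param wavelengths overrides `profile$wavelengths`.
#' @return integer band indices, sorted by wavelength, with attribute
#'   `"wavelengths"`.
#' @export
select_sensitive_bands <- function(profile, k = 7L, min_separation = 20,
                                   wavelengths = NULL) {
  wl <- if (!is.null(wavelengths)) wavelengths else profile$wavelengths
  if (is.null(wl)) stop("wavelengths required for band selection")
  s <- abs(profile$S)
  if (k < 1L) stop("k must be >= 1")
  ord <- order(-s, wl)
  chosen <- integer(0)
  for (b in ord) {
    if (length(chosen) == k) break
    if (!length(chosen) || all(abs(wl[b] - wl[chosen]) >= min_separation))
      chosen <- c(chosen, b)
  }
  if (length(chosen) < k) {
    kmax <- max_feasible_bands(wl, min_separation)
    stop("cannot place ", k, " bands ", min_separation,
         " nm apart; maximum feasible k is ", min(kmax, length(chosen)))
  }
  out <- sort(chosen)
  attr(out, "wavelengths") <- wl[out]
  out
}

# largest number of bands placeable with pairwise separation >= sep
# (greedy left-to-right sweep is optimal for interval packing on a line)
max_feasible_bands <- function(wl, sep) {
  wl <- sort(wl)
  n <- 0L; last <- -Inf
  for (w in wl) if (w - last >= sep || n == 0L) { n <- n + 1L; last <- w }
  n
}

#' Correlation-block partition of the band axis
#'
#' Computes the band-to-band Pearson correlation over unmasked pixels, takes
#' the adjacent-band correlation vector r_b = corr(b, b+1), and cuts the band
#' axis wherever r_b is a local minimum below `theta`. Contiguous runs of
#' highly inter-correlated bands form the subspaces from which representative
#' bands are drawn.
#'
#' @inheritParams pca_features
#' @param theta cut threshold on adjacent-band correlation (default 0.90).
#' @return object of class `band_subspaces`: list with `starts` (first band
#'   index of each subspace, 1-based), `membership` (length-B subspace id),
#'   `adjacent_corr` (length B-1), `corr` (B x B), `theta`.
#' @export
asp_band_partition <- function(cube, mask = NULL, theta = 0.90) {
  px <- cube_pixels(cube, mask)
  B <- ncol(px$x)
  if (B < 3L) stop("need at least 3 bands")
  if (nrow(px$x) < 2L) stop("need at least 2 unmasked pixels")
  sds <- apply(px$x, 2, stats::sd)
  if (any(sds == 0))
    warning("constant band(s): ", paste(which(sds == 0), collapse = ", "),
            "; their correlations are defined as 0")
  cm <- matrix(0, B, B)
  ok <- sds > 0
  if (any(ok)) cm[ok, ok] <- stats::cor(px$x[, ok, drop = FALSE])
  diag(cm) <- 1
  r <- cm[cbind(seq_len(B - 1L), seq(2L, B))]
  # cut after band b where r_b is a local minimum (ties allowed) below theta
  is_min <- vapply(seq_len(B - 1L), function(b) {
    left_ok <- b == 1L || r[b] <= r[b - 1L]
    right_ok <- b == B - 1L || r[b] <= r[b + 1L]
    left_ok && right_ok
  }, logical(1))
  cuts <- which(is_min & r < theta)
  starts <- c(1L, cuts + 1L)
  membership <- findInterval(seq_len(B), starts)
  structure(list(starts = starts, membership = membership,
                 adjacent_corr = r, corr = cm, theta = theta),
            class = "band_subspaces")
}

#' @export
print.band_subspaces <- function(x, ...) {
  cat("band_subspaces:", length(x$starts), "subspace(s), starts at band(s)",
      paste(x$starts, collapse = ", "), "\n")
  invisible(x)
}

# medoid of one subspace: band maximizing the sum of |corr| to the other
# members; ties broken toward the band nearest the subspace centre, then the
# lowest index
subspace_medoid <- function(members, cm) {
  if (length(members) == 1L) return(members)
  score <- vapply(members, function(b)
    sum(abs(cm[b, setdiff(members, b)])), numeric(1))
  best <- members[score == max(score)]
  if (length(best) > 1L) {
    centre <- (min(members) + max(members)) / 2
    d <- abs(best - centre)
    best <- best[d == min(d)]
  }
  min(best)
}

#' Representative bands from a subspace partition
#'
#' One medoid band per subspace (the member with the largest summed absolute
#' correlation to the rest of its subspace). If `k` is smaller than the number
#' of subspaces, the k subspaces with the highest total band variance keep
#' their representatives; if larger, the widest subspaces are split at their
#' midpoints until k representatives exist.
#'
#' @param subspaces a [asp_band_partition()] result.
#' @param cube the cube the partition came from.
#' @param mask optional extra exclusion mask.
#' @param k number of bands (default 7).
#' @return integer band indices sorted by wavelength, attribute
#'   `"wavelengths"`.
#' @export
select_representative_bands <- function(subspaces, cube, mask = NULL, k = 7L) {
  px <- cube_pixels(cube, mask)
  cm <- subspaces$corr
  groups <- split(seq_along(subspaces$membership), subspaces$membership)
  if (any(!lengths(groups))) stop("empty subspace")
  if (length(groups) > k) {
    vars <- vapply(groups, function(g)
      sum(apply(px$x[, g, drop = FALSE], 2, stats::var)), numeric(1))
    groups <- groups[order(-vars)[seq_len(k)]]
  } else {
    while (length(groups) < k) {
      sizes <- lengths(groups)
      if (max(sizes) < 2L)
        stop("cannot select ", k, " bands from ", length(groups),
             " indivisible subspace(s)")
      g <- groups[[which.max(sizes)]]
      half <- ceiling(length(g) / 2)
      groups[[which.max(sizes)]] <- g[seq_len(half)]
      groups <- c(groups, list(g[-seq_len(half)]))
    }
  }
  bands <- sort(vapply(groups, subspace_medoid, integer(1), cm = cm))
  attr(bands, "wavelengths") <- cube$wavelengths[bands]
  bands
}

#' Feature stack from a set of selected bands
#'
#' @param cube a [reflectance_cube()].
#' @param bands integer band indices.
#' @param method label stored on the stack (`"ss"` or `"bc"`).
#' @return a [feature_stack()] whose feature names are the band wavelengths.
#' @export
band_feature_stack <- function(cube, bands, method = "bands") {
  data <- cube$data[, , bands, drop = FALSE]
  data[array(cube$mask, dim = dim(data))] <- NA_real_
  feature_stack(data, sprintf("%.0fnm", cube$wavelengths[bands]), method)
}

#' Z-score features over unmasked pixels
#'
#' Makes Euclidean distance comparable across feature constructors; applied by
#' default before clustering. Zero-variance features are left centred.
#'
#' @param stack a [feature_stack()].
#' @return the standardized stack.
#' @export
standardize_features <- function(stack) {
  d <- dim(stack$data)
  flat <- matrix(stack$data, d[1] * d[2], d[3])
  for (j in seq_len(d[3])) {
    v <- flat[, j]
    ok <- is.finite(v)
    mu <- mean(v[ok]); s <- stats::sd(v[ok])
    flat[, j] <- if (is.na(s) || s == 0) v - mu else (v - mu) / s
  }
  stack$data <- array(flat, dim = d)
  stack
}
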