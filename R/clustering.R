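## Pixel clustering: K-means (Lloyd, seeded restarts, empty-cluster reseed),
## fuzzy C-means, and density-peak clustering, plus the evaluation-time
## cluster -> {ground, healthy, infected} assignment. All clusterers operate
## on an N x F feature matrix; the pipeline reshapes maps to and from it.

#' Clustering result
#'
#' @param labels integer N-vector (or H x W matrix) of cluster ids in
#'   `[0, K)`; -1 for masked pixels.
#' @param K number of clusters.
#' @param centers K x F matrix of cluster centres in feature space.
#' @param extra optional list of method diagnostics (e.g. membership matrix,
#'   density-peak state).
#' @return object of class `cluster_map`.
#' @export
cluster_map <- function(labels, K, centers, extra = list()) {
  structure(c(list(labels = labels, K = as.integer(K), centers = centers),
              extra),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("cluster_map: K =", x$K, "sizes:",
      paste(tabulate(unlist(x$labels) + 1L, x$K), collapse = ", "), "\n")
  invisible(x)
}

squared_dist_to_centers <- function(x, centers) {
  # N x K matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

#' K-means clustering (Lloyd's algorithm)
#'
#' Squared-Euclidean assignment, centroid update, seeded random restarts; the
#' best restart by within-cluster sum of squares wins. An emptied cluster is
#' reseeded at the point farthest from its assigned centre.
#'
#' @param features N x F numeric matrix.
#' @param K number of clusters (default 3: ground / healthy / infected).
#' @param seed RNG seed; fixed seed gives a bit-identical result.
#' @param n_init random restarts (default 10).
#' @param max_iter Lloyd iterations per restart.
#' @return a [cluster_map()] with `wcss` in the extras.
#' @export
kmeans_cluster <- function(features, K = 3L, seed = 1L, n_init = 10L,
                           max_iter = 100L) {
  features <- as.matrix(features)
  N <- nrow(features)
  if (K > N) stop("K (", K, ") exceeds number of points (", N, ")")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- features[sample.int(N, K), , drop = FALSE]
      assign_prev <- rep(-1L, N)
      for (it in seq_len(max_iter)) {
        d2 <- squared_dist_to_centers(features, centers)
        assign <- max.col(-d2, ties.method = "first")
        for (k in seq_len(K)) {
          if (!any(assign == k)) {           # reseed at the farthest point
            far <- which.max(d2[cbind(seq_len(N), assign)])
            centers[k, ] <- features[far, ]
            assign[far] <- k
          }
        }
        if (all(assign == assign_prev)) break
        assign_prev <- assign
        for (k in seq_len(K))
          centers[k, ] <- colMeans(features[assign == k, , drop = FALSE])
      }
      wcss <- sum((features - centers[assign, , drop = FALSE])^2)
      if (is.null(best) || wcss < best$wcss)
        best <- list(assign = assign, centers = centers, wcss = wcss)
    }
  })
  cluster_map(best$assign - 1L, K, best$centers, list(wcss = best$wcss))
}

#' Fuzzy C-means clustering
#'
#' Alternates the membership update
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and the centre update
#' `w_i = sum_k u_ik^m x_k / sum_k u_ik^m` until the summed squared centre
#' shift drops below `tol`. A point coincident with a centre takes membership
#' 1 there (the limit convention). Hard labels are the row-wise maximum
#' membership.
#'
#' @inheritParams kmeans_cluster
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence threshold on the squared centre shift.
#' @param n_init seeded random restarts; the run with the lowest fuzzy
#'   objective `J = sum_ik u_ik^m d_ik^2` wins (the alternating updates only
#'   find a local optimum of J, so a single initialization can park a centre
#'   on a dense sub-region).
#' @return a [cluster_map()]; extras hold the N x K `membership` matrix,
#'   objective value and iteration count.
#' @export
fcm_cluster <- function(features, K = 3L, m = 2, tol = 1e-5, max_iter = 300L,
                        seed = 1L, n_init = 5L) {
  features <- as.matrix(features)
  N <- nrow(features)
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (K > N) stop("K exceeds number of points")
  expo <- -1 / (m - 1)  # applied to squared distances = d^(-2/(m-1))
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- features[sample.int(N, K), , drop = FALSE]
      iter <- 0L
      repeat {
        iter <- iter + 1L
        d2 <- pmax(squared_dist_to_centers(features, centers), 0)
        u <- matrix(0, N, K)
        hit <- d2 < .Machine$double.eps
        exact <- rowSums(hit) > 0
        if (any(exact)) {
          u[exact, ] <- hit[exact, , drop = FALSE] /
            rowSums(hit[exact, , drop = FALSE])
        }
        if (any(!exact)) {
          p <- d2[!exact, , drop = FALSE]^expo
          u[!exact, ] <- p / rowSums(p)
        }
        um <- u^m
        new_centers <- t(um) %*% features / colSums(um)
        e <- sum((new_centers - centers)^2)
        centers <- new_centers
        if (e < tol || iter >= max_iter) break
      }
      J <- sum((u^m) * pmax(squared_dist_to_centers(features, centers), 0))
      if (is.null(best) || J < best$J)
        best <- list(u = u, centers = centers, J = J, iter = iter)
    }
  })
  cluster_map(max.col(best$u, ties.method = "first") - 1L, K, best$centers,
              list(membership = best$u, objective = best$J,
                   iterations = best$iter))
}

## --- density-peak clustering ------------------------------------------------

# rho/delta/parent under the cutoff or gaussian kernel; ties in density are
# ordered by index (among equal densities, the earlier point counts as denser)
dp_state_from_dist <- function(d, dc, kernel) {
  N <- nrow(d)
  rho <- if (kernel == "cutoff") {
    as.integer(rowSums(d < dc) - 1L)   # self-distance 0 always counts; drop it
  } else {
    rowSums(exp(-(d / dc)^2)) - 1
  }
  ord <- order(-rho, seq_len(N))       # decreasing density, index tie-break
  delta <- numeric(N)
  parent <- integer(N)
  delta[ord[1]] <- max(d[ord[1], ])
  parent[ord[1]] <- 0L
  for (i in seq(2L, length.out = N - 1L)) {
    higher <- ord[seq_len(i - 1L)]
    di <- d[ord[i], higher]
    j <- which.min(di)
    delta[ord[i]] <- di[j]
    parent[ord[i]] <- higher[j]
  }
  list(rho = rho, delta = delta, parent = parent, order = ord,
       gamma = rho * delta, dc = dc)
}

#' Density-peak clustering
#'
#' Local density `rho_i` counts neighbours within the truncation distance
#' `d_c` (cutoff kernel); `delta_i` is the distance to the nearest
#' strictly-denser point, or the maximum pairwise distance for the global
#' density peak. The K points with the largest `gamma = rho * delta` become
#' cluster centres, and every other point inherits the label of its nearest
#' denser neighbour, visited in decreasing-density order. Ties in density are
#' broken by index (the lower index is treated as denser), making the result
#' deterministic.
#'
#' For N above `max_fit_points` the decision graph is fitted on a seeded
#' uniform subsample (the O(N^2) distance matrix is the cost driver) and the
#' remaining points are assigned to the nearest centre.
#'
#' @inheritParams kmeans_cluster
#' @param dc_percentile quantile of pairwise distances defining `d_c`
#'   (default 0.05: on spatially smoothed features large uniform regions
#'   concentrate much of the pairwise-distance mass near zero, and a lower
#'   quantile can fall below that plateau scale, making the density count
#'   degenerate).
#' @param kernel `"cutoff"` (integer densities; default) or `"gaussian"`.
#' @param max_fit_points subsample budget for the decision graph.
#' @return a [cluster_map()]; extras hold the `dp_state` (rho, delta, gamma,
#'   dc, parent, fitted index set).
#' @export
dp_cluster <- function(features, K = 3L, dc_percentile = 0.05,
                       kernel = c("cutoff", "gaussian"),
                       max_fit_points = 8000L, seed = 1L) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  N <- nrow(features)
  if (K < 1L || K > N) stop("need 1 <= K <= N")
  fit_idx <- if (N > max_fit_points)
    sort(with_seed(seed, sample.int(N, max_fit_points)))
  else seq_len(N)
  X <- features[fit_idx, , drop = FALSE]
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  pd <- d[upper.tri(d)]
  if (all(pd == 0)) {
    warning("all points identical: single cluster regardless of K")
    return(cluster_map(rep(0L, N), 1L, X[1, , drop = FALSE],
                       list(dp_state = list(rho = rep(n - 1L, n),
                                            delta = rep(0, n), dc = 0,
                                            gamma = rep(0, n),
                                            fit_idx = fit_idx))))
  }
  dc <- stats::quantile(pd, dc_percentile, names = FALSE)
  if (dc == 0) dc <- min(pd[pd > 0])
  st <- dp_state_from_dist(d, dc, kernel)
  centers_i <- order(-st$gamma, seq_len(n))[seq_len(K)]
  lab <- rep(NA_integer_, n)
  lab[centers_i] <- seq_len(K) - 1L
  for (i in st$order) {
    if (is.na(lab[i])) lab[i] <- lab[st$parent[i]]
  }
  centers <- X[centers_i, , drop = FALSE]
  labels <- integer(N)
  labels[fit_idx] <- lab
  out_idx <- setdiff(seq_len(N), fit_idx)
  if (length(out_idx)) {
    d2 <- squared_dist_to_centers(features[out_idx, , drop = FALSE], centers)
    labels[out_idx] <- max.col(-d2, ties.method = "first") - 1L
  }
  st$fit_idx <- fit_idx
  st$center_idx <- fit_idx[centers_i]
  cluster_map(labels, K, centers, list(dp_state = st))
}

## --- cluster -> class assignment -------------------------------------------

#' Map cluster ids to semantic classes using reference labels
#'
#' Builds the cluster x class overlap table over reference-labeled pixels and
#' chooses the injective cluster-to-class assignment maximizing the number of
#' correctly labeled pixels (exhaustive search over assignments; K <= 7).
#' A cluster with no labeled pixels is assigned the modal reference class,
#' with a warning.
#'
#' @param clusters integer vector/matrix of cluster ids in `[0, K)` (-1
#'   ignored).
#' @param reference a [label_map()] or integer vector/matrix of reference
#'   class ids (-1 = unlabeled), same length/extent.
#' @param K number of clusters (inferred if missing).
#' @param n_classes number of semantic classes (defaults to reference).
#' @return integer vector `mapping` of length K (`mapping[k+1]` = class id of
#'   cluster k), with attribute `"class_labels"`: `clusters` relabeled.
#' @export
map_clusters_to_classes <- function(clusters, reference, K = NULL,
                                    n_classes = NULL) {
  ref <- if (inherits(reference, "label_map")) reference$labels else reference
  cl_raw <- if (inherits(clusters, "cluster_map")) clusters$labels else clusters
  out_dims <- dim(cl_raw)
  cl <- as.integer(cl_raw); ref <- as.integer(ref)
  if (length(cl) != length(ref)) stop("extent mismatch")
  if (is.null(K)) K <- max(cl) + 1L
  if (is.null(n_classes)) {
    n_classes <- if (inherits(reference, "label_map"))
      length(reference$class_names) else max(ref) + 1L
  }
  if (!any(ref >= 0L)) stop("no labeled reference pixels")
  if (K > 7L) stop("exhaustive assignment supports K <= 7")
  ov <- matrix(0, K, n_classes)
  sel <- ref >= 0L & cl >= 0L
  tab <- table(factor(cl[sel], levels = 0:(K - 1L)),
               factor(ref[sel], levels = 0:(n_classes - 1L)))
  ov[] <- as.numeric(tab)
  unseen <- rowSums(ov) == 0
  active <- which(!unseen)
  if (length(active) > n_classes)
    stop("more non-empty clusters (", length(active),
         ") than reference classes (", n_classes, ")")
  best <- NULL; best_score <- -1
  for (p in all_permutations(n_classes)) {
    cls <- (p - 1L)[seq_along(active)]
    score <- sum(ov[cbind(active, cls + 1L)])
    if (score > best_score) { best_score <- score; best <- cls }
  }
  mapping <- integer(K)
  mapping[active] <- best
  if (any(unseen)) {
    modal <- which.max(tabulate(ref[ref >= 0L] + 1L, n_classes)) - 1L
    mapping[which(unseen)] <- modal
    warning("cluster(s) ", paste(which(unseen) - 1L, collapse = ", "),
            " overlap no labeled pixels; assigned modal class ", modal)
  }
  out <- cl
  out[cl >= 0L] <- mapping[cl[cl >= 0L] + 1L]
  if (!is.null(out_dims)) out <- matrix(out, out_dims[1], out_dims[2])
  structure(mapping, class_labels = out, score = best_score)
}

#' Label-free cluster -> class heuristic
#'
#' Deployment-mode rule when no reference ROI exists: the cluster with the
#' lowest mean NDVI is ground; of the remaining clusters, the one with the
#' lowest mean near-infrared reflectance is infected; the rest are healthy.
#' Only defined for K = 3.
#'
#' @param clusters cluster ids (vector or matrix, `[0,3)`).
#' @param cube the [reflectance_cube()] the clusters came from.
#' @return integer mapping of length 3 as in [map_clusters_to_classes()].
#' @export
map_clusters_heuristic <- function(clusters, cube) {
  cl <- if (inherits(clusters, "cluster_map")) clusters$labels else clusters
  cl <- as.integer(cl)
  if (max(cl) + 1L != 3L) stop("heuristic mapping requires K = 3")
  ndvi <- as.vector(vegetation_index(cube, "ndvi"))
  nir <- as.vector(cube$data[, , nearest_band(cube$wavelengths, 800, 790, 860,
                                              "near-infrared")])
  mean_ndvi <- vapply(0:2, function(k) mean(ndvi[cl == k]), numeric(1))
  ground <- which.min(mean_ndvi) - 1L
  rest <- setdiff(0:2, ground)
  mean_nir <- vapply(rest, function(k) mean(nir[cl == k]), numeric(1))
  infected <- rest[which.min(mean_nir)]
  healthy <- setdiff(rest, infected)
  mapping <- integer(3)
  mapping[ground + 1L] <- 0L
  mapping[healthy + 1L] <- 1L
  mapping[infected + 1L] <- 2L
  out <- cl
  out[cl >= 0L] <- mapping[cl[cl >= 0L] + 1L]
  structure(mapping, class_labels = out)
}
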