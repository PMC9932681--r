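## End-to-end orchestration of the 4-feature x 3-clusterer experiment grid:
## (optional background masking) -> spectral features -> WSSMF -> clustering
## -> cluster-to-class mapping -> accuracy evaluation. Every default a field
## campaign leaves open (gamma mode, d_c percentile, theta, ...) is echoed in
## the metrics so runs are auditable.

FEATURE_METHODS <- c("pca", "lle", "ss", "bc")
CLUSTERERS <- c("kmeans", "fcm", "dp")

#' Pipeline configuration
#'
#' @param feature_method one of `"pca"` (principal components), `"lle"`
#'   (locally linear embedding), `"ss"` (spectral-sensitivity band selection),
#'   `"bc"` (band clustering / subspace partition).
#' @param clusterer one of `"kmeans"`, `"fcm"`, `"dp"`.
#' @param K number of clusters (default 3: ground / healthy / infected).
#' @param n_components components for pca/lle (default 4).
#' @param n_bands bands for ss/bc (default 7).
#' @param min_separation minimum wavelength gap (nm) for ss selection.
#' @param theta adjacent-correlation cut threshold for bc.
#' @param filter a [filter_params()], or `NULL` to skip spatial filtering.
#' @param standardize z-score features before clustering (default TRUE).
#' @param mask_method `"none"` (default; ground is clustered as a class) or
#'   `"ndvi"` (Otsu-masked background pixels are assigned directly to class
#'   0 = ground and clustering runs on vegetation only).
#' @param seed global seed; per-stage seeds are derived at fixed offsets.
#' @param dc_percentile,lle_neighbors,fcm_m tunables forwarded to the stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_method = "bc", clusterer = "dp", K = 3L,
                            n_components = 4L, n_bands = 7L,
                            min_separation = 20, theta = 0.90,
                            filter = filter_params(), standardize = TRUE,
                            mask_method = c("none", "ndvi"), seed = 1L,
                            dc_percentile = 0.05, lle_neighbors = 12L,
                            fcm_m = 2) {
  if (!feature_method %in% FEATURE_METHODS)
    stop("unknown feature_method '", feature_method, "'; must be one of ",
         paste(FEATURE_METHODS, collapse = ", "))
  if (!clusterer %in% CLUSTERERS)
    stop("unknown clusterer '", clusterer, "'; must be one of ",
         paste(CLUSTERERS, collapse = ", "))
  mask_method <- match.arg(mask_method)
  structure(list(feature_method = feature_method, clusterer = clusterer,
                 K = as.integer(K), n_components = as.integer(n_components),
                 n_bands = as.integer(n_bands),
                 min_separation = min_separation, theta = theta,
                 filter = filter, standardize = isTRUE(standardize),
                 mask_method = mask_method, seed = as.integer(seed),
                 dc_percentile = dc_percentile,
                 lle_neighbors = as.integer(lle_neighbors), fcm_m = fcm_m),
            class = "pipeline_config")
}

# class means of the unfiltered cube over reference labels; used by the
# spectral-sensitivity constructor (healthy = 1, infected = 2)
reference_spectra <- function(cube, labels) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  lab <- as.integer(labels$labels)
  list(healthy = colMeans(flat[lab == 1L, , drop = FALSE]),
       stressed = colMeans(flat[lab == 2L, , drop = FALSE]))
}

# feature construction stage; returns a feature_stack and a description of
# what was selected/extracted
build_features <- function(cube, config, labels = NULL, mask = NULL) {
  switch(config$feature_method,
    pca = {
      fs <- pca_features(cube, mask, config$n_components)
      list(stack = fs,
           info = list(explained_variance_ratio =
                         attr(fs, "explained_variance_ratio")))
    },
    lle = {
      fs <- lle_features(cube, mask, n_neighbors = config$lle_neighbors,
                         n_components = config$n_components,
                         seed = config$seed + 211L)
      list(stack = fs, info = list(n_neighbors = config$lle_neighbors))
    },
    ss = {
      if (is.null(labels))
        stop("spectral sensitivity requires reference labels for the ",
             "healthy/stressed mean spectra")
      rs <- reference_spectra(cube, labels)
      prof <- spectral_sensitivity(rs$stressed, rs$healthy, cube$wavelengths)
      bands <- select_sensitive_bands(prof, k = config$n_bands,
                                      min_separation = config$min_separation)
      list(stack = band_feature_stack(cube, bands, "ss"),
           info = list(bands = as.integer(bands),
                       wavelengths_nm = attr(bands, "wavelengths")))
    },
    bc = {
      sub <- asp_band_partition(cube, mask, theta = config$theta)
      bands <- select_representative_bands(sub, cube, mask, k = config$n_bands)
      list(stack = band_feature_stack(cube, bands, "bc"),
           info = list(bands = as.integer(bands),
                       wavelengths_nm = attr(bands, "wavelengths"),
                       n_subspaces = length(sub$starts)))
    })
}

run_clusterer <- function(x, config) {
  switch(config$clusterer,
    kmeans = kmeans_cluster(x, config$K, seed = config$seed + 101L),
    fcm = fcm_cluster(x, config$K, m = config$fcm_m,
                      seed = config$seed + 102L),
    dp = dp_cluster(x, config$K, dc_percentile = config$dc_percentile,
                    seed = config$seed + 103L))
}

#' Run one recognition model end-to-end
#'
#' @param cube a [reflectance_cube()].
#' @param labels a [label_map()] of reference classes (required for
#'   evaluation and for the `"ss"` feature method).
#' @param config a [pipeline_config()].
#' @return list of class `model_result`: `class_map` (H x W class ids),
#'   `cluster_map`, `confusion` (if labels given), `metrics` (OA, kappa,
#'   per-class producer/user accuracy, feature info, all parameters).
#' @export
run_model <- function(cube, labels = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- dim(cube$data)
  bg <- NULL
  if (config$mask_method == "ndvi") {
    veg <- mask_background(vegetation_index(cube, "ndvi"), "otsu")
    bg <- !veg
  }
  feats <- build_features(cube, config, labels, mask = bg)
  stack <- feats$stack
  if (config$standardize) stack <- standardize_features(stack)
  if (!is.null(config$filter)) stack <- wssmf(stack, config$filter)
  flat <- matrix(stack$data, d[1] * d[2], dim(stack$data)[3])
  keep <- rowSums(!is.finite(flat)) == 0
  if (!any(keep)) stop("empty pixel set after masking")
  cm <- run_clusterer(flat[keep, , drop = FALSE], config)
  clusters <- rep(-1L, d[1] * d[2])
  clusters[keep] <- cm$labels
  class_ids <- rep(-1L, d[1] * d[2])
  if (!is.null(labels)) {
    ref <- as.integer(labels$labels)
    ref_eval <- ref
    if (!is.null(bg)) ref_eval[as.vector(bg)] <- -1L  # mapped separately
    mapping <- map_clusters_to_classes(clusters, ref_eval, K = config$K,
                                       n_classes = length(labels$class_names))
    class_ids <- attr(mapping, "class_labels")
  } else {
    mapping <- map_clusters_heuristic(clusters, cube)
    class_ids <- attr(mapping, "class_labels")
  }
  if (!is.null(bg)) class_ids[as.vector(bg)] <- 0L  # masked background = ground
  class_map <- matrix(class_ids, d[1], d[2])
  result <- list(class_map = class_map,
                 cluster_map = matrix(clusters, d[1], d[2]),
                 mapping = as.integer(mapping))
  if (!is.null(labels)) {
    conf <- confusion_matrix(class_map, labels)
    pu <- producer_user_accuracy(conf)
    result$confusion <- conf
    result$metrics <- list(
      model = paste(config$feature_method, config$clusterer, sep = "-"),
      oa = overall_accuracy(conf),
      kappa = kappa_coefficient(conf),
      producer = as.list(pu$producer), user = as.list(pu$user),
      feature_info = feats$info,
      params = unclass(config)[setdiff(names(config), "filter")],
      filter = if (is.null(config$filter)) NULL else unclass(config$filter))
  }
  class(result) <- "model_result"
  result
}

#' Run the full feature x clusterer grid
#'
#' Features are constructed once per method and shared by the three
#' clusterers. Failures in one cell are recorded and the grid continues.
#'
#' @inheritParams run_model
#' @param config a [pipeline_config()]; its `feature_method`/`clusterer` are
#'   ignored, the grid spans all of them.
#' @return list of class `grid_result`: `table` (one row per model with OA
#'   and kappa), `confusions` (named list), `pooled_by_feature`,
#'   `pooled_by_clusterer` (entrywise-summed confusion matrices), `errors`.
#' @export
run_grid <- function(cube, labels, config = pipeline_config()) {
  rows <- list(); confs <- list(); errors <- list()
  for (fm in FEATURE_METHODS) {
    for (clu in CLUSTERERS) {
      cfg <- config
      cfg$feature_method <- fm
      cfg$clusterer <- clu
      id <- paste(fm, clu, sep = "_")
      res <- tryCatch(run_model(cube, labels, cfg), error = function(e) e)
      if (inherits(res, "error")) {
        errors[[id]] <- conditionMessage(res)
        next
      }
      confs[[id]] <- res$confusion
      rows[[id]] <- data.frame(feature = fm, clusterer = clu,
                               oa = res$metrics$oa,
                               kappa = res$metrics$kappa)
    }
  }
  tab <- do.call(rbind, rows)
  by_feat <- lapply(stats::setNames(FEATURE_METHODS, FEATURE_METHODS),
                    function(fm)
                      pool_confusions(confs[grep(paste0("^", fm, "_"),
                                                 names(confs))]))
  by_clu <- lapply(stats::setNames(CLUSTERERS, CLUSTERERS),
                   function(clu)
                     pool_confusions(confs[grep(paste0("_", clu, "$"),
                                                names(confs))]))
  structure(list(table = tab, confusions = confs,
                 pooled_by_feature = by_feat, pooled_by_clusterer = by_clu,
                 errors = errors),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  tab <- x$table
  tab$oa <- sprintf("%.2f%%", 100 * tab$oa)
  tab$kappa <- sprintf("%.3f", tab$kappa)
  print(tab, row.names = TRUE)
  if (length(x$errors))
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
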