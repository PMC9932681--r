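#' Hyperspectral reflectance cube
#'
#' Container for an H x W x B reflectance image with its wavelength vector and
#' an optional per-pixel exclusion mask. Reflectance is unitless in \[0, 1\];
#' wavelengths are in nanometres and strictly increasing. Pixels are addressed
#' row-major with the band axis last.
#'
#' @param data numeric H x W x B array of reflectance values.
#' @param wavelengths numeric vector of length B, strictly increasing, in nm.
#' @param mask logical H x W matrix; `TRUE` marks pixels excluded from all
#'   computation (nodata / background). Defaults to all `FALSE`.
#' @return An object of class `reflectance_cube`: a list with elements
#'   `data`, `wavelengths`, `mask`.
#' @export
reflectance_cube <- function(data, wavelengths, mask = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (H x W x B)")
  dims <- dim(data)
  if (dims[3] != length(wavelengths))
    stop("band count (", dims[3], ") must equal length(wavelengths) (",
         length(wavelengths), ")")
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (is.null(mask)) mask <- matrix(FALSE, dims[1], dims[2])
  if (!is.logical(mask) || !all(dim(mask) == dims[1:2]))
    stop("`mask` must be a logical H x W matrix")
  keep <- !mask
  vals <- data[array(keep, dim = dims)]
  if (any(!is.finite(vals)))
    stop("non-finite reflectance on unmasked pixels")
  if (any(vals < 0))
    stop("negative reflectance on unmasked pixels")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 mask = mask),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("reflectance_cube: %d x %d pixels, %d bands (%.0f-%.0f nm), %d masked\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              sum(x$mask)))
  invisible(x)
}

#' @export
dim.reflectance_cube <- function(x) dim(x$data)

#' Per-pixel class label raster
#'
#' Integer labels per pixel: 0 = ground, 1 = healthy, 2 = infected by default,
#' -1 = unlabeled. Class ids index into `class_names` (id k -> k+1-th name).
#'
#' @param labels integer H x W matrix with values in `{-1} U [0, K)`.
#' @param class_names character vector of K class names.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, class_names = c("ground", "healthy", "infected")) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  k <- length(class_names)
  bad <- labels[labels != -1L]
  if (length(bad) && (min(bad) < 0L || max(bad) >= k))
    stop("labels must lie in {-1} U [0, ", k, ")")
  structure(list(labels = labels, class_names = class_names),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1, seq_along(x$class_names) - 1L),
                      labels = c("unlabeled", x$class_names)))
  cat("label_map:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Cube I/O.  Two dialects:
##   "envi"  — ENVI text header (.hdr) + raw binary (.img), BSQ interleave,
##             little-endian 32-bit float (the single supported variant, so
##             files are bit-reproducible); nodata mask, when present, is
##             persisted as a companion <path>.msk uint8 raster.
##   "plain" — a single RDS file holding the named list
##             (data, wavelengths, mask); lossless at double precision.
## ---------------------------------------------------------------------------

#' Write a reflectance cube to disk
#'
#' @param cube a [reflectance_cube()].
#' @param path output path. For the ENVI dialect this is the binary image file;
#'   the header is written alongside as `<path>.hdr`.
#' @param dialect `"envi"` (BSQ, float32, little-endian) or `"plain"` (RDS).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cube, "reflectance_cube"))
  if (dialect == "plain") {
    saveRDS(list(data = cube$data, wavelengths = cube$wavelengths,
                 mask = cube$mask), path)
    return(invisible(path))
  }
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {specmite reflectance cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                 collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: sample (column) fastest, then line, then band
  v <- as.vector(aperm(cube$data, c(2, 1, 3)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  mskfile <- paste0(path, ".msk")
  if (any(cube$mask)) {
    mcon <- file(mskfile, "wb")
    writeBin(as.integer(as.vector(t(cube$mask))), mcon, size = 1L)
    close(mcon)
  } else if (file.exists(mskfile)) {
    unlink(mskfile)
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # join { ... } blocks that span lines
  joined <- character()
  open <- ""
  for (ln in lines) {
    if (nzchar(open)) {
      open <- paste(open, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, open); open <- "" }
    } else if (grepl("\\{", ln) && !grepl("\\}", ln)) {
      open <- ln
    } else {
      joined <- c(joined, ln)
    }
  }
  kv <- joined[grepl("=", joined)]
  keys <- tolower(trimws(sub("=.*", "", kv)))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Read a reflectance cube from disk
#'
#' @param path file written by [write_cube()] (for ENVI, the binary file with
#'   its `.hdr` alongside).
#' @inheritParams write_cube
#' @return A [reflectance_cube()].
#' @export
read_cube <- function(path, dialect = c("envi", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plain") {
    obj <- readRDS(path)
    if (!all(c("data", "wavelengths") %in% names(obj)))
      stop("plain-array container must hold 'data' and 'wavelengths'")
    return(reflectance_cube(obj$data, obj$wavelengths, obj$mask))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header lacks field(s): ",
                         paste(miss, collapse = ", "))
  W <- as.integer(h$samples); H <- as.integer(h$lines)
  B <- as.integer(h$bands)
  if (as.integer(h[["data type"]]) != 4L)
    stop("unsupported ENVI data type (only 4 = float32)")
  if (tolower(h$interleave) != "bsq")
    stop("unsupported ENVI interleave (only bsq)")
  n_expect <- as.numeric(H) * W * B
  n_have <- file.size(path) / 4
  if (n_have != n_expect)
    stop("header declares ", B, " band(s) of ", H, "x", W,
         " but file holds ", n_have / (as.numeric(H) * W), " band(s)")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
  if (any(!is.finite(v))) stop("non-finite values in ENVI payload")
  data <- aperm(array(v, dim = c(W, H, B)), c(2, 1, 3))
  wl <- h$wavelength
  if (is.null(wl)) stop("ENVI header lacks wavelength block")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
  if (length(wl) != B) stop("wavelength count differs from band count")
  mask <- NULL
  mskfile <- paste0(path, ".msk")
  if (file.exists(mskfile)) {
    mcon <- file(mskfile, "rb")
    mv <- readBin(mcon, "integer", n = H * W, size = 1L)
    close(mcon)
    mask <- matrix(as.logical(mv), H, W, byrow = TRUE)
  }
  reflectance_cube(data, wl, mask)
}

## ---------------------------------------------------------------------------
## Vegetation indices and background masking
## ---------------------------------------------------------------------------

# nearest band to a target wavelength, constrained to lie inside [lo, hi]
nearest_band <- function(wavelengths, target, lo, hi, region) {
  b <- which.min(abs(wavelengths - target))
  if (wavelengths[b] < lo || wavelengths[b] > hi)
    stop("no band in the ", region, " region (", lo, "-", hi, " nm); ",
         "nearest is ", wavelengths[b], " nm")
  b
}

#' Vegetation index image
#'
#' NDVI = (NIR - Red) / (NIR + Red) with bands mapped to spectral regions by
#' nearest wavelength (Red target 670 nm within 660-680, NIR target 800 nm
#' within 790-860). VDVI = (2G - R - B') / (2G + R + B') using nearest-band
#' proxies (G 550, R 670, B' 460 nm); VDVI is experimental — the blue proxy is
#' the short-wavelength edge of a typical 450-900 nm grid.
#'
#' Zero-denominator pixels are set to 0 and reported via the `"invalid"`
#' attribute (logical H x W).
#'
#' @param cube a [reflectance_cube()].
#' @param index `"ndvi"` (default) or `"vdvi"`.
#' @return numeric H x W matrix in \[-1, 1\] with attribute `"invalid"`.
#' @export
vegetation_index <- function(cube, index = c("ndvi", "vdvi")) {
  index <- match.arg(index)
  wl <- cube$wavelengths
  if (index == "ndvi") {
    red <- cube$data[, , nearest_band(wl, 670, 660, 680, "red")]
    nir <- cube$data[, , nearest_band(wl, 800, 790, 860, "near-infrared")]
    num <- nir - red
    den <- nir + red
  } else {
    g <- cube$data[, , nearest_band(wl, 550, 500, 600, "green")]
    r <- cube$data[, , nearest_band(wl, 670, 620, 700, "red")]
    b <- cube$data[, , nearest_band(wl, 460, 440, 510, "blue-proxy")]
    num <- 2 * g - r - b
    den <- 2 * g + r + b
  }
  invalid <- den == 0
  out <- ifelse(invalid, 0, num / den)
  out <- pmin(pmax(out, -1), 1)
  attr(out, "invalid") <- invalid
  out
}

#' Otsu threshold of an index image
#'
#' Maximizes between-class variance over a 256-bin histogram of the finite
#' values. Errors on a constant image (no separable classes).
#'
#' @param x numeric vector or matrix.
#' @param nbins number of histogram bins.
#' @return the threshold (bin upper edge), a scalar.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- x[is.finite(x)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold undefined (no separable classes)")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  # between-class variance for threshold after bin t
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_idx <- which.max(sigma_b)
  breaks[t_idx + 1L]
}

#' Vegetation / background mask from an index image
#'
#' @param index_image numeric H x W matrix (e.g. from [vegetation_index()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required when `method = "fixed"`.
#' @return logical H x W matrix, `TRUE` = vegetation (index >= threshold),
#'   with attribute `"threshold"`.
#' @export
mask_background <- function(index_image, method = c("otsu", "fixed"),
                            threshold = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(index_image)))
    stop("index image must be finite")
  t <- if (method == "fixed") {
    if (is.null(threshold)) stop("`threshold` required for method = 'fixed'")
    threshold
  } else {
    otsu_threshold(index_image)
  }
  m <- index_image >= t
  attr(m, "threshold") <- t
  attr(m, "invalid") <- NULL
  m
}
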