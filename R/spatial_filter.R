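## Weighted spatial-spectral mean filtering (WSSMF).
##
## Each unmasked pixel is replaced by a similarity-weighted mean of its w x w
## spatial neighbourhood: neighbours whose spectra resemble the centre get
## weight close to 1, dissimilar neighbours (across a class edge) are
## down-weighted, so noise is suppressed without blurring region boundaries.
##
##   out_ij = sum_pq w_pq x_pq / sum_pq w_pq,   w_pq = exp(-gamma0 ||x_ij - x_pq||^2)
##
## gamma0 is recomputed per pixel from its own neighbourhood:
##   paper-literal : mean Euclidean distance from the centre to all
##                   neighbourhood members (the centre's zero self-distance
##                   included in the mean) — note the distance units inside
##                   exp(-gamma0 d^2); kept as the faithful default.
##   inverse-mean  : 1 / (mean distance)^2, the dimensionally conventional
##                   reading (the exponent becomes a squared distance ratio).
## The centre always participates with weight exp(0) = 1.

#' Filter parameters for WSSMF
#'
#' @param window odd window width in pixels (default 5).
#' @param gamma_mode `"paper-literal"` (mean neighbourhood distance, default)
#'   or `"inverse-mean"` (its inverse square).
#' @param edge_mode `"shrink"` (clip the neighbourhood at image borders and
#'   renormalize, default) or `"reflect"` (mirror padding).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(window = 5L,
                          gamma_mode = c("paper-literal", "inverse-mean"),
                          edge_mode = c("shrink", "reflect")) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  structure(list(window = window, gamma_mode = match.arg(gamma_mode),
                 edge_mode = match.arg(edge_mode)),
            class = "filter_params")
}

# shift a matrix by (dr, dc); out-of-range cells NA
shift_matrix <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  out
}

reflect_pad <- function(m, a) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(min(a, H - 1)) + 1L), seq_len(H),
          H - seq_len(min(a, H - 1)))
  ci <- c(rev(seq_len(min(a, W - 1)) + 1L), seq_len(W),
          W - seq_len(min(a, W - 1)))
  m[ri, ci, drop = FALSE]
}

#' Weighted spatial-spectral mean filter
#'
#' @param x a [reflectance_cube()], [feature_stack()], 3-d array, or H x W
#'   matrix (treated as a single band).
#' @param params a [filter_params()].
#' @param mask optional logical H x W matrix of pixels to exclude (combined
#'   with the object's own mask / NA pixels). Masked pixels are neither
#'   filtered nor used as neighbours; their values pass through unchanged.
#' @return same class and shape as `x`.
#' @export
wssmf <- function(x, params = filter_params(), mask = NULL) {
  if (inherits(x, "reflectance_cube")) {
    out <- x
    m <- if (is.null(mask)) x$mask else (mask | x$mask)
    out$data <- wssmf_array(x$data, params, mask = m)
    return(out)
  }
  if (inherits(x, "feature_stack")) {
    out <- x
    nam <- matrix(is.na(x$data[, , 1]), dim(x$data)[1], dim(x$data)[2])
    m <- if (is.null(mask)) nam else (mask | nam)
    out$data <- wssmf_array(x$data, params, mask = m)
    return(out)
  }
  if (is.matrix(x))
    return(wssmf_array(array(x, dim = c(dim(x), 1L)), params, mask)[, , 1])
  wssmf_array(x, params, mask)
}

wssmf_array <- function(arr, params, mask = NULL) {
  d <- dim(arr)
  H <- d[1]; W <- d[2]; F <- d[3]
  w <- params$window
  if (w > min(H, W)) stop("window (", w, ") larger than image (", H, "x", W, ")")
  if (w == 1L) return(arr)
  a <- (w - 1L) %/% 2L
  if (is.null(mask)) mask <- matrix(FALSE, H, W)
  orig_dims <- c(H, W)
  pad <- params$edge_mode == "reflect"
  if (pad) {
    arr <- array(apply(arr, 3, reflect_pad, a = a),
                 dim = c(H + 2L * a, W + 2L * a, F))
    mask <- reflect_pad(mask * 1, a) > 0
    H <- H + 2L * a; W <- W + 2L * a
  }
  bands <- lapply(seq_len(F), function(b) arr[, , b])
  for (b in seq_len(F)) bands[[b]][mask] <- NA_real_
  offsets <- expand.grid(dr = -a:a, dc = -a:a)
  n_off <- nrow(offsets)
  dist2 <- vector("list", n_off)
  valid <- vector("list", n_off)
  sum_d <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (o in seq_len(n_off)) {
    dr <- offsets$dr[o]; dc <- offsets$dc[o]
    d2 <- matrix(0, H, W)
    ok <- matrix(TRUE, H, W)
    for (b in seq_len(F)) {
      sb <- shift_matrix(bands[[b]], dr, dc)
      diffb <- bands[[b]] - sb
      ok <- ok & !is.na(sb)
      diffb[is.na(diffb)] <- 0
      d2 <- d2 + diffb^2
    }
    d2[!ok] <- 0
    dist2[[o]] <- d2
    valid[[o]] <- ok
    sum_d <- sum_d + sqrt(d2) * ok
    cnt <- cnt + ok
  }
  mean_d <- sum_d / pmax(cnt, 1)
  gamma0 <- switch(params$gamma_mode,
    "paper-literal" = mean_d,
    "inverse-mean" = ifelse(mean_d > 0, 1 / mean_d^2, 0))
  num <- vector("list", F)
  for (b in seq_len(F)) num[[b]] <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (o in seq_len(n_off)) {
    wt <- exp(-gamma0 * dist2[[o]]) * valid[[o]]
    den <- den + wt
    for (b in seq_len(F)) {
      sb <- shift_matrix(bands[[b]], offsets$dr[o], offsets$dc[o])
      sb[!valid[[o]]] <- 0
      num[[b]] <- num[[b]] + wt * sb
    }
  }
  out <- arr
  proc <- !mask & den > 0
  for (b in seq_len(F)) {
    layer <- arr[, , b]
    layer[proc] <- num[[b]][proc] / den[proc]
    out[, , b] <- layer
  }
  if (pad) out <- out[a + seq_len(orig_dims[1]), a + seq_len(orig_dims[2]), ,
                      drop = FALSE]
  out
}
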