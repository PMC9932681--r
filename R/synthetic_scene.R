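## Synthetic three-class hyperspectral scenes (ground / healthy canopy /
## mite-infested canopy). The generator reproduces the statistical structure
## the recognition pipeline assumes: infested vegetation reflects more than
## healthy vegetation throughout the visible (450-730 nm) and markedly less on
## the near-infrared plateau (780-900 nm); ground is spectrally flat. Class
## geometry comes from thresholding a smoothed Gaussian random field, giving
## irregular canopy-like patches; boundary pixels are linear template
## mixtures (the mixed-pixel effect); band noise is i.i.d. Gaussian.

#' Parameters of a synthetic scene
#'
#' @param height,width scene extent in pixels.
#' @param wavelengths band centres in nm (default 45 bands over 450-900 nm).
#' @param class_templates 3 x B reflectance templates, rows ground / healthy /
#'   infected (defaults to [default_templates()]).
#' @param class_fractions proportions of ground, healthy, infected pixels;
#'   must sum to 1. The default 0.60/0.27/0.13 mirrors the labeled-pixel
#'   ratio of the benchmark survey (11213/5036/2438).
#' @param blob_scale Gaussian smoothing sigma (pixels) of the label field;
#'   larger values give coarser patches.
#' @param noise_sd i.i.d. Gaussian band noise SD in reflectance units.
#' @param mixing_width boundary half-width in pixels within which pixels are
#'   mixtures of the two adjacent class templates.
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       wavelengths = seq(450, 900, length.out = 45L),
                       class_templates = default_templates(wavelengths),
                       class_fractions = c(ground = 0.60, healthy = 0.27,
                                           infected = 0.13),
                       blob_scale = 12, noise_sd = 0.01, mixing_width = 1L,
                       seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(class_templates < 0 | class_templates > 1))
    stop("templates must lie in [0, 1]")
  if (ncol(class_templates) != length(wavelengths))
    stop("template band count mismatch")
  structure(list(height = as.integer(height), width = as.integer(width),
                 wavelengths = wavelengths,
                 class_templates = class_templates,
                 class_fractions = class_fractions,
                 blob_scale = blob_scale, noise_sd = noise_sd,
                 mixing_width = as.integer(mixing_width),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Canopy-stress reflectance templates
#'
#' Parametric shapes: healthy canopy is dark in the visible (small green bump
#' at 550 nm) with a logistic red edge centred at 755 nm rising to a 0.50
#' near-infrared plateau; infested canopy is strictly brighter throughout
#' 450-730 nm (chlorosis) with a weaker, later red edge reaching only 0.35
#' (strictly below healthy at 780-900 nm, cell-structure damage); ground is
#' spectrally flat mid-reflectance with a mild upward slope.
#'
#' @param wavelengths band centres in nm; must cover 450-900 nm.
#' @return 3 x B matrix, rows `ground`, `healthy`, `infected`.
#' @export
default_templates <- function(wavelengths) {
  if (min(wavelengths) > 450 || max(wavelengths) < 900)
    stop("wavelengths must cover 450-900 nm")
  wl <- wavelengths
  healthy <- 0.06 + 0.04 * exp(-((wl - 550) / 30)^2) +
    0.44 / (1 + exp(-(wl - 755) / 8))
  infected <- 0.11 + 0.05 * exp(-((wl - 560) / 45)^2) +
    0.24 / (1 + exp(-(wl - 760) / 10))
  ground <- 0.22 + 0.0001 * (wl - 450)
  out <- rbind(ground = ground, healthy = healthy, infected = infected)
  pmin(pmax(out, 0), 1)
}

# separable Gaussian smoothing with reflecting boundaries
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, min(ceiling(3 * sigma), min(dim(m)) - 1L))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    ri <- min(r, n - 1)
    padded <- c(v[(ri + 1):2], v, v[(n - 1):(n - ri)])
    as.numeric(stats::filter(padded, k, sides = 2))[(ri + 1):(ri + n)]
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

# Chebyshev distance (up to maxd) from each pixel to the nearest pixel of a
# different class, together with that pixel's class
boundary_distance <- function(labels, maxd) {
  H <- nrow(labels); W <- ncol(labels)
  dist <- matrix(Inf, H, W)
  other <- matrix(NA_integer_, H, W)
  if (maxd < 1L) return(list(dist = dist, other = other))
  for (d in seq_len(maxd)) {
    ring <- expand.grid(dr = -d:d, dc = -d:d)
    ring <- ring[pmax(abs(ring$dr), abs(ring$dc)) == d, ]
    for (i in seq_len(nrow(ring))) {
      sh <- shift_int_matrix(labels, ring$dr[i], ring$dc[i])
      hit <- !is.na(sh) & sh != labels & dist > d
      dist[hit] <- d
      other[hit] <- sh[hit]
    }
  }
  list(dist = dist, other = other)
}

shift_int_matrix <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_integer_, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  out
}

#' Generate a synthetic scene
#'
#' The label field thresholds a blob-scale-smoothed Gaussian random field at
#' the class-fraction quantiles (realized fractions match the requested ones
#' up to ties). Pure pixels are their class template plus i.i.d. band noise,
#' clipped to \[0, 1\]. Pixels within `mixing_width` (Chebyshev) of a class
#' boundary are linear mixtures with the nearest foreign template; the mixing
#' coefficient is `alpha = U * (mixing_width - d + 1) / (mixing_width + 1)`
#' with `U ~ Uniform(0, 1/2)` — sub-pixel boundary position varies
#' continuously, so mixed pixels form a continuous spectral bridge between
#' the class clouds rather than discrete phantom classes, and alpha stays
#' below 1/2 so the pixel's label (its majority component) is well defined.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `cube` (a [reflectance_cube()]) and `labels`
#'   (a [label_map()]; 0 = ground, 1 = healthy, 2 = infected).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  B <- length(spec$wavelengths)
  with_seed(spec$seed, {
    field <- gauss_smooth(matrix(stats::rnorm(H * W), H, W), spec$blob_scale)
    cuts <- stats::quantile(field, cumsum(spec$class_fractions)[1:2],
                            names = FALSE)
    labels <- matrix(findInterval(field, cuts), H, W)  # 0, 1, 2
    tmpl <- spec$class_templates
    flat <- tmpl[labels + 1L, , drop = FALSE]          # (H*W) x B, column-major
    if (spec$mixing_width >= 1L) {
      bd <- boundary_distance(labels, spec$mixing_width)
      mixed <- which(is.finite(bd$dist))
      if (length(mixed)) {
        alpha <- stats::runif(length(mixed), 0, 0.5) *
          (spec$mixing_width - bd$dist[mixed] + 1) / (spec$mixing_width + 1)
        flat[mixed, ] <- (1 - alpha) * flat[mixed, , drop = FALSE] +
          alpha * tmpl[bd$other[mixed] + 1L, , drop = FALSE]
      }
    }
    if (spec$noise_sd > 0)
      flat <- flat + matrix(stats::rnorm(H * W * B, sd = spec$noise_sd),
                            H * W, B)
    flat <- pmin(pmax(flat, 0), 1)
    cube <- reflectance_cube(array(flat, dim = c(H, W, B)), spec$wavelengths)
    list(cube = cube, labels = label_map(labels))
  })
}
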