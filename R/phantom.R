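# Synthetic lung-CT phantom: bright elliptical lung fields on a dark
# background with an embedded hyperdense tumor disc, plus controllable
# multiplicative speckle and salt-and-pepper impulses. Gives every pipeline
# stage a ground truth without any data download.

#' Phantom specification
#'
#' The default emulates a 128 x 128 axial chest slice: dark background
#' (0.05), two lung-field ellipses at 0.35, and a 8-pixel-radius tumor disc
#' at 0.85 inside the left lung — intensity-separable classes, but
#' noise-sensitive once speckle is applied. Coordinates are (row, col) with
#' origin 1 at the top-left; `axes` are ellipse half-lengths in pixels.
#'
#' @param height,width Image size in pixels.
#' @param background_level Background intensity in \[0, 1\].
#' @param lung_ellipses List of lung fields, each
#'   `list(center = c(r, c), axes = c(ar, ac), level = ...)`.
#' @param tumor_disc `list(center = c(r, c), radius = , level = )`; must lie
#'   inside a lung ellipse with level above the lung level.
#' @param speckle_var Variance of the multiplicative Gaussian speckle
#'   applied to the noisy rendering (0 = none).
#' @param impulse_frac Fraction of pixels replaced by salt-and-pepper
#'   impulses in the noisy rendering.
#' @param seed Integer seed for the noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         background_level = 0.05,
                         lung_ellipses = list(
                           list(center = c(64, 38), axes = c(42, 22),
                                level = 0.35),
                           list(center = c(64, 92), axes = c(42, 22),
                                level = 0.35)),
                         tumor_disc = list(center = c(56, 44), radius = 8,
                                           level = 0.85),
                         speckle_var = 0.05, impulse_frac = 0, seed = 1L) {
  levels <- c(background_level,
              vapply(lung_ellipses, `[[`, numeric(1), "level"),
              tumor_disc$level)
  if (any(levels < 0 | levels > 1))
    stop_param("all levels must lie in [0, 1]")
  if (tumor_disc$level <= max(vapply(lung_ellipses, `[[`, numeric(1),
                                     "level")))
    stop_param("tumor level must exceed the lung level (tumor is hyperdense)")
  if (speckle_var < 0) stop_param("speckle_var must be nonnegative")
  if (impulse_frac < 0 || impulse_frac >= 1)
    stop_param("impulse_frac must lie in [0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background_level = background_level,
                 lung_ellipses = lung_ellipses, tumor_disc = tumor_disc,
                 speckle_var = speckle_var, impulse_frac = impulse_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1L]) / axes[1L])^2 + ((c - center[2L]) / axes[2L])^2 <= 1
}

#' Render a lung phantom with known tumor ground truth
#'
#' Renders the piecewise-constant regions of `spec` (background, lung
#' ellipses, tumor disc, in that order), then applies the configured speckle
#' and impulse noise under `spec$seed`. Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `clean` (noise-free image), `image` (noisy rendering;
#'   equals `clean` when both noise levels are zero), `truth` (binary tumor
#'   mask) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level, h, w)
  lung <- matrix(FALSE, h, w)
  for (e in spec$lung_ellipses) {
    m <- ellipse_mask(h, w, e$center, e$axes)
    img[m] <- e$level
    lung <- lung | m
  }
  td <- spec$tumor_disc
  disc <- ellipse_mask(h, w, td$center, c(td$radius, td$radius))
  if (any(disc & !lung))
    stop_param("invalid phantom: tumor disc extends outside the lung fields")
  img[disc] <- td$level
  noisy <- img
  if (spec$speckle_var > 0)
    noisy <- add_speckle(noisy, spec$speckle_var, spec$seed)
  if (spec$impulse_frac > 0)
    noisy <- add_impulses(noisy, spec$impulse_frac, spec$seed + 1L)
  list(clean = img, image = noisy, truth = disc + 0, spec = spec)
}

#' Add multiplicative Gaussian speckle
#'
#' Returns `clip(img * (1 + eta), 0, 1)` with i.i.d.
#' \eqn{\eta \sim N(0, \mathrm{variance})} per pixel; `variance = 0` is the
#' identity.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param variance Nonnegative noise variance.
#' @param seed Integer seed.
#' @export
add_speckle <- function(img, variance, seed = 1L) {
  check_image(img)
  if (length(variance) != 1L || variance < 0)
    stop_param("variance must be nonnegative")
  if (variance == 0) return(img)
  eta <- with_seed(seed,
                   matrix(stats::rnorm(length(img), 0, sqrt(variance)),
                          nrow(img), ncol(img)))
  pmin(pmax(img * (1 + eta), 0), 1)
}

#' Add salt-and-pepper impulses
#'
#' Exactly `round(frac * npixels)` pixels, sampled without replacement, are
#' set to 0 or 1 with equal probability. The corrupted coordinates and the
#' values written are attached as attribute `"impulses"` (a data frame with
#' columns `row`, `col`, `value`).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param frac Fraction of pixels to corrupt, in \[0, 1).
#' @param seed Integer seed.
#' @export
add_impulses <- function(img, frac, seed = 1L) {
  check_image(img)
  if (length(frac) != 1L || frac < 0 || frac >= 1)
    stop_param("frac must lie in [0, 1)")
  if (frac == 0) return(img)
  n <- length(img)
  n_corrupt <- round(frac * n)
  out <- img
  hit <- with_seed(seed, {
    idx <- sample.int(n, n_corrupt)
    val <- sample(c(0, 1), n_corrupt, replace = TRUE)
    list(idx = idx, val = val)
  })
  out[hit$idx] <- hit$val
  attr(out, "impulses") <- data.frame(
    row = ((hit$idx - 1L) %% nrow(img)) + 1L,
    col = ((hit$idx - 1L) %/% nrow(img)) + 1L,
    value = hit$val)
  out
}
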