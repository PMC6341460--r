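#' Median filter
#'
#' Replaces each pixel by the median of its `window` x `window`
#' neighborhood, the classical speckle remover for CT. Borders are handled by
#' edge replication, so every window is full size.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param window Odd window side length (pixels), >= 3.
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  check_image(img)
  window <- check_odd_window(window)
  median_filter_cpp(img, window)
}

#' Adaptive median filter
#'
#' Two-stage scheme with a per-pixel window that grows while the window
#' median is an extreme (equal to the window minimum or maximum), up to
#' `smax`; the final stage passes non-extreme pixels through unchanged and
#' replaces extreme (impulse-like) pixels by the window median. Preserves
#' edges and fine structure that the plain median filter blurs.
#'
#' @inheritParams median_filter
#' @param smax Maximum (odd) window side length, >= `window`.
#' @export
adaptive_median_filter <- function(img, window = 3L, smax = 7L) {
  check_image(img)
  window <- check_odd_window(window)
  smax <- check_odd_window(smax, "smax")
  if (smax < window)
    stop_param("smax must be >= window")
  adaptive_median_filter_cpp(img, window, smax)
}

#' Average (mean) filter
#'
#' Replaces each pixel by the arithmetic mean of its neighborhood; edge
#' replication at borders.
#'
#' @inheritParams median_filter
#' @export
average_filter <- function(img, window = 3L) {
  check_image(img)
  window <- check_odd_window(window)
  average_filter_cpp(img, window)
}

# Quantize unit intensities to 1..levels bins.
quantize_levels <- function(img, levels) {
  pmin(floor(img * levels) + 1L, levels)
}

#' Global histogram equalization
#'
#' Intensities are quantized to `levels` bins and each pixel is mapped to the
#' cumulative mass of its bin (the fraction of pixels at or below its level),
#' so output values lie in (0, 1\] and the mapping is monotone nondecreasing:
#' the rank order of distinct intensities is preserved.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param levels Number of gray levels (>= 2), default 256.
#' @export
global_hist_equalize <- function(img, levels = 256L) {
  check_image(img)
  if (length(levels) != 1L || !is.finite(levels) || levels < 2)
    stop_param("levels must be an integer >= 2")
  levels <- as.integer(levels)
  b <- quantize_levels(img, levels)
  h <- tabulate(b, nbins = levels)
  cdf <- cumsum(h) / length(img)
  out <- matrix(cdf[b], nrow(img), ncol(img))
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is split into a `tiles[1]` x `tiles[2]` grid; each tile's
#' histogram is clipped at `clip` times the tile pixel count per bin, the
#' excess redistributed uniformly, and the clipped CDF used as that tile's
#' intensity mapping. Pixels are transformed by bilinear interpolation
#' between the mappings of the four nearest tile centers (clamped at the
#' image border). With a single tile and `clip = 1` this reduces exactly to
#' [global_hist_equalize()].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param tiles Integer pair: tile grid rows and columns.
#' @param clip Clip limit as a fraction of the tile pixel count, in (0, 1\].
#' @param levels Number of histogram bins (default 256).
#' @export
clahe <- function(img, tiles = c(8L, 8L), clip = 0.01, levels = 256L) {
  check_image(img)
  if (length(tiles) != 2L || any(!is.finite(tiles)) || any(tiles < 1))
    stop_param("tiles must be two integers >= 1")
  if (length(clip) != 1L || !is.finite(clip) || clip <= 0 || clip > 1)
    stop_param("clip must lie in (0, 1]")
  tiles <- as.integer(tiles)
  levels <- as.integer(levels)
  nr <- nrow(img); nc <- ncol(img)
  tr <- min(tiles[1L], nr); tc <- min(tiles[2L], nc)

  # tile boundaries (as equal as possible) and centers
  row_edges <- round(seq(0L, nr, length.out = tr + 1L))
  col_edges <- round(seq(0L, nc, length.out = tc + 1L))
  row_ctr <- (row_edges[-1L] + row_edges[-(tr + 1L)] + 1) / 2
  col_ctr <- (col_edges[-1L] + col_edges[-(tc + 1L)] + 1) / 2

  b <- quantize_levels(img, levels)
  # per-tile clipped-CDF lookup tables: array [tr, tc, levels]
  lut <- array(0, c(tr, tc, levels))
  for (i in seq_len(tr)) {
    ri <- (row_edges[i] + 1L):row_edges[i + 1L]
    for (j in seq_len(tc)) {
      cj <- (col_edges[j] + 1L):col_edges[j + 1L]
      bt <- b[ri, cj]
      h <- tabulate(bt, nbins = levels)
      npix <- length(bt)
      clipcount <- clip * npix
      excess <- sum(pmax(h - clipcount, 0))
      h <- pmin(h, clipcount) + excess / levels
      lut[i, j, ] <- cumsum(h) / npix
    }
  }

  # bilinear interpolation between tile-center mappings
  interp_axis <- function(coords, centers) {
    n <- length(centers)
    i0 <- findInterval(coords, centers)
    i0 <- pmin(pmax(i0, 1L), n)
    i1 <- pmin(i0 + 1L, n)
    denom <- centers[i1] - centers[i0]
    w0 <- ifelse(denom > 0, (centers[i1] - coords) / denom, 1)
    w0 <- pmin(pmax(w0, 0), 1)
    list(i0 = i0, i1 = i1, w0 = w0)
  }
  ry <- interp_axis(seq_len(nr), row_ctr)
  cx <- interp_axis(seq_len(nc), col_ctr)

  rowv <- rep(seq_len(nr), times = nc)
  colv <- rep(seq_len(nc), each = nr)
  bv <- as.vector(b)
  wy0 <- ry$w0[rowv]; wx0 <- cx$w0[colv]
  g <- function(ii, jj) lut[cbind(ii[rowv], jj[colv], bv)]
  outv <- wy0 * wx0 * g(ry$i0, cx$i0) +
    wy0 * (1 - wx0) * g(ry$i0, cx$i1) +
    (1 - wy0) * wx0 * g(ry$i1, cx$i0) +
    (1 - wy0) * (1 - wx0) * g(ry$i1, cx$i1)
  matrix(outv, nr, nc)
}
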