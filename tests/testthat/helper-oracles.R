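# Independent brute-force oracles, deliberately naive: plain R loops with
# sort-and-pick semantics, no shared code with the implementation.

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

window_values <- function(img, i, j, w) {
  h <- w %/% 2
  rows <- clamp_idx((i - h):(i + h), nrow(img))
  cols <- clamp_idx((j - h):(j + h), ncol(img))
  as.vector(img[rows, cols])
}

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

median_filter_oracle <- function(img, w) {
  out <- img
  for (j in seq_len(ncol(img)))
    for (i in seq_len(nrow(img)))
      out[i, j] <- oracle_median(window_values(img, i, j, w))
  out
}

average_filter_oracle <- function(img, w) {
  out <- img
  for (j in seq_len(ncol(img)))
    for (i in seq_len(nrow(img)))
      out[i, j] <- mean(window_values(img, i, j, w))
  out
}

# Exhaustive optimum of the squared-distance objective over all 2-partitions
# of the distinct intensities (centers = weighted means of the two parts).
exhaustive_k2_optimum <- function(img) {
  vals <- sort(unique(as.vector(img)))
  cnt <- tabulate(match(as.vector(img), vals), nbins = length(vals))
  m <- length(vals)
  best <- Inf
  for (bits in 1:(2^m - 2)) {
    in1 <- as.logical(bitwAnd(bits, 2^(seq_len(m) - 1)))
    c1 <- sum(cnt[in1] * vals[in1]) / sum(cnt[in1])
    c2 <- sum(cnt[!in1] * vals[!in1]) / sum(cnt[!in1])
    best <- min(best, objective_j(img, c(c1, c2)))
  }
  best
}

# Direct evaluation of the validity fitness from its definition: nearest
# assignment by explicit distance comparison, occupancy-weighted separation
# over the worst-cluster scatter.
fitness_oracle <- function(pixels, centers, eps = 1e-9) {
  k <- length(centers)
  lab <- vapply(pixels, function(x) which.min(abs(x - centers)), integer(1))
  intra <- 0
  for (i in seq_len(k)) {
    if (!any(lab == i)) next
    intra <- max(intra, mean(abs(pixels[lab == i] - centers[i])))
  }
  intra <- max(intra, eps)
  f <- 0
  for (i in seq_len(k)) {
    if (!any(lab == i)) next
    f <- f + (sum(lab == i) / length(pixels)) *
      mean(abs(centers[i] - centers[-i])) / intra
  }
  f
}

# Small two-level test image: values lo/hi in a fixed block pattern.
two_level_image <- function(n = 16, lo = 0.2, hi = 0.8) {
  img <- matrix(lo, n, n)
  img[(n %/% 4):(n %/% 2), (n %/% 4):(n %/% 2)] <- hi
  img
}

random_mask <- function(n, p, seed) {
  withr::with_seed(seed, matrix(rbinom(n * n, 1, p), n, n))
}

# Hand-built swarm state for step-level tests (bypasses swarm_segment).
manual_state <- function(positions, velocities, fitness_fn, gc = FALSE,
                         rho = 1) {
  fit <- apply(positions, 1, fitness_fn)
  swarmseg:::new_swarm_state(positions, velocities, fit, gc = gc, rho = rho)
}
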