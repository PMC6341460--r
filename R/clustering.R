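# Intensity clustering: pixels are clustered in 1-D grayscale space.
# Internally images are compressed to (distinct value, count) pairs, which is
# exact for 1-D Lloyd iterations and keeps large rasters cheap.

value_table <- function(img) {
  v <- sort(unique(as.vector(img)))
  w <- tabulate(match(as.vector(img), v), nbins = length(v))
  list(values = v, weights = w)
}

# Nearest-center assignment with ties broken to the lowest center index.
assign_nearest <- function(values, centers) {
  d <- abs(outer(values, centers, "-"))
  max.col(-d, ties.method = "first")
}

# Weighted median matching stats::median on unit weights (even total mass at
# the split point -> mean of the two adjacent values).
weighted_median <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  i <- which(cw >= tot / 2)[1L]
  if (cw[i] == tot / 2 && i < length(v)) (v[i] + v[i + 1L]) / 2 else v[i]
}

#' Sum-of-squares clustering objective
#'
#' \eqn{J(v) = \sum_i \|x_i - v_{c(i)}\|^2} where each pixel \eqn{x_i} is
#' assigned to its nearest center \eqn{v_{c(i)}}.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param centers Numeric vector of cluster centers.
#' @return Nonnegative scalar.
#' @export
objective_j <- function(img, centers) {
  check_image(img)
  if (length(centers) < 1L)
    stop_param("centers must be nonempty")
  vt <- value_table(img)
  lab <- assign_nearest(vt$values, centers)
  sum(vt$weights * (vt$values - centers[lab])^2)
}

# Sum of absolute deviations objective (k-median).
objective_l1 <- function(img, centers) {
  vt <- value_table(img)
  lab <- assign_nearest(vt$values, centers)
  sum(vt$weights * abs(vt$values - centers[lab]))
}

new_cluster_model <- function(method, img, centers, objective, trace,
                              n_iter, converged, extra = list()) {
  o <- order(centers)
  centers <- centers[o]
  vt <- value_table(img)
  lab_values <- assign_nearest(vt$values, centers)
  labels <- matrix(lab_values[match(as.vector(img), vt$values)],
                   nrow(img), ncol(img))
  structure(
    c(list(method = method, k = length(centers), centers = centers,
           labels = labels, objective = objective,
           objective_trace = trace, n_iter = n_iter, converged = converged),
      extra),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$method, ", k = ", x$k, "\n", sep = "")
  cat("  centers:  ", paste(signif(x$centers, 5), collapse = ", "), "\n")
  cat("  objective:", signif(x$objective, 6),
      " (", x$n_iter, " iterations",
      if (isTRUE(x$converged)) ", converged" else "", ")\n", sep = "")
  invisible(x)
}

lloyd_run <- function(vt, k, seed, tol, max_iter, median_update) {
  values <- vt$values; weights <- vt$weights
  centers <- with_seed(seed, sample(values, k))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  obj_fun <- if (median_update) {
    function(lab, ctr) sum(weights * abs(values - ctr[lab]))
  } else {
    function(lab, ctr) sum(weights * (values - ctr[lab])^2)
  }
  while (it < max_iter) {
    it <- it + 1L
    lab <- assign_nearest(values, centers)
    new_centers <- centers
    for (j in seq_len(k)) {
      m <- lab == j
      if (!any(m)) {
        # empty-cluster repair: jump to the value farthest from this center
        new_centers[j] <- values[which.max(abs(values - centers[j]))]
      } else if (median_update) {
        new_centers[j] <- weighted_median(values[m], weights[m])
      } else {
        new_centers[j] <- sum(weights[m] * values[m]) / sum(weights[m])
      }
    }
    lab <- assign_nearest(values, new_centers)
    trace <- c(trace, obj_fun(lab, new_centers))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  list(centers = centers, objective = trace[length(trace)], trace = trace,
       n_iter = it, converged = converged)
}

cluster_segment <- function(img, k, tol, max_iter, seed, restarts,
                            median_update, method) {
  check_image(img)
  if (length(k) != 1L || k < 2) stop_param("k must be an integer >= 2")
  k <- as.integer(k)
  vt <- value_table(img)
  if (length(vt$values) < k)
    stop_param("degenerate input: only ", length(vt$values),
               " distinct intensities for k = ", k)
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- lloyd_run(vt, k, seed + r - 1L, tol, max_iter, median_update)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  new_cluster_model(method, img, best$centers, best$objective, best$trace,
                    best$n_iter, best$converged)
}

#' k-means intensity segmentation
#'
#' Lloyd iterations on pixel intensities: assign each pixel to its nearest
#' center (ties to the lowest index), recompute centers as member means,
#' until the largest center shift falls below `tol` or `max_iter` is
#' reached. Centers are initialized by seeded sampling of `k` distinct pixel
#' values; `restarts` independent starts are run and the lowest-objective
#' solution kept. Empty clusters are repaired by moving the center to the
#' pixel value farthest from it. Returned centers are sorted ascending with
#' labels renumbered accordingly, so cluster identities are canonical.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param k Number of clusters, >= 2.
#' @param tol Convergence tolerance on the maximum center shift.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param restarts Number of seeded restarts.
#' @return A `cluster_model` with sorted `centers`, integer `labels`
#'   (1..k, image-shaped), the squared-distance `objective`, its per-iteration
#'   `objective_trace` (nonincreasing), `n_iter` and `converged`.
#' @export
kmeans_segment <- function(img, k = 3L, tol = 1e-6, max_iter = 300L,
                           seed = 1L, restarts = 10L) {
  cluster_segment(img, k, tol, max_iter, seed, restarts,
                  median_update = FALSE, method = "kmeans")
}

#' k-median intensity segmentation
#'
#' As [kmeans_segment()] but centers are recomputed as member medians and the
#' objective is the sum of absolute deviations, avoiding the squaring that
#' makes k-means sensitive to outlying intensities.
#'
#' @inheritParams kmeans_segment
#' @export
kmedian_segment <- function(img, k = 3L, tol = 1e-6, max_iter = 300L,
                            seed = 1L, restarts = 10L) {
  cluster_segment(img, k, tol, max_iter, seed, restarts,
                  median_update = TRUE, method = "kmedian")
}
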