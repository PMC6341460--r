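#' Swarm configuration
#'
#' Collects every tunable of the particle-swarm segmenters. Defaults follow
#' the standard settings for intensity clustering on the unit interval:
#' constant inertia weight `w = 0.7` (random mode redraws `w = 0.5 + U(0,1)/2`
#' once per iteration, shared by all particles), success/failure thresholds
#' `sc = 15`, `fc = 5` with search-radius expansion x2 and contraction x0.5,
#' 30 particles, 100 iterations, acceleration coefficients `c1 = c2 = 2`,
#' and a velocity clamp of one fifth of the intensity range.
#'
#' @param n_particles Number of particles (>= 2).
#' @param max_iter Maximum iterations.
#' @param c1,c2 Positive acceleration coefficients (cognitive, social).
#' @param w_mode `"constant"`, `"random"`, or `"none"` (plain PSO, no
#'   inertia term).
#' @param w Inertia weight used in constant mode.
#' @param v_max Velocity clamp per dimension.
#' @param bounds Length-2 search interval for centers.
#' @param sc,fc Consecutive-success / consecutive-failure thresholds driving
#'   the guaranteed-convergence search radius.
#' @param rho0 Initial search radius (scaled by the bounds width).
#' @param rho_expand,rho_contract Radius multipliers applied after more than
#'   `sc` successes / `fc` failures.
#' @param patience Stop after this many iterations without global-best
#'   improvement (`Inf` disables).
#' @param fitness_bins Histogram resolution for fitness evaluation; `0`
#'   evaluates exactly on the per-pixel intensity list.
#' @param restarts Independent seeded swarm runs; the run with the best
#'   final global-best fitness wins. Multi-start is the standard guard
#'   against premature convergence of a collapsed swarm into a local
#'   optimum of the validity fitness.
#' @param seed Integer seed for all randomness in [swarm_segment()]; restart
#'   r runs under `seed + 1000 (r - 1)`.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30L, max_iter = 100L,
                         c1 = 2, c2 = 2,
                         w_mode = c("constant", "random", "none"), w = 0.7,
                         v_max = 0.2, bounds = c(0, 1),
                         sc = 15L, fc = 5L,
                         rho0 = 1, rho_expand = 2, rho_contract = 0.5,
                         patience = 25L, fitness_bins = 256L, restarts = 5L,
                         seed = 1L) {
  w_mode <- match.arg(w_mode)
  if (n_particles < 2) stop_param("n_particles must be >= 2")
  if (c1 < 0 || c2 < 0) stop_param("c1 and c2 must be nonnegative")
  if (v_max <= 0) stop_param("v_max must be positive")
  if (length(bounds) != 2L || bounds[2L] <= bounds[1L])
    stop_param("bounds must be an increasing length-2 interval")
  if (sc < 1 || fc < 1) stop_param("sc and fc must be positive integers")
  if (rho0 <= 0) stop_param("rho0 must be positive")
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 w_mode = w_mode, w = w, v_max = v_max, bounds = bounds,
                 sc = as.integer(sc), fc = as.integer(fc), rho0 = rho0,
                 rho_expand = rho_expand, rho_contract = rho_contract,
                 patience = patience, fitness_bins = as.integer(fitness_bins),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "swarm_config")
}

# (values, weights) compression of an image for fitness evaluation: exact
# per-pixel list (bins = 0) or a `bins`-bin intensity histogram, equivalent
# for 1-D intensities up to quantization and much cheaper on large rasters.
fitness_support <- function(img, bins = 0L) {
  if (bins > 0L) {
    b <- quantize_levels(img, bins)
    w <- tabulate(b, nbins = bins)
    keep <- w > 0L
    list(values = ((seq_len(bins) - 0.5) / bins)[keep], weights = w[keep])
  } else {
    value_table(img)
  }
}

cluster_fitness_vw <- function(values, weights, centers, eps = 1e-9) {
  k <- length(centers)
  lab <- assign_nearest(values, centers)
  n <- sum(weights)
  # per-cluster occupancy (pixel share) and scatter (mean member-center
  # absolute distance); the denominator is the worst-cluster scatter
  intra <- 0
  mass <- numeric(k)
  for (i in seq_len(k)) {
    m <- lab == i
    if (!any(m)) next
    wi <- sum(weights[m])
    mass[i] <- wi / n
    intra <- max(intra, sum(weights[m] * abs(values[m] - centers[i])) / wi)
  }
  intra <- max(intra, eps)
  total <- 0
  for (i in which(mass > 0))                # empty clusters contribute 0
    total <- total + mass[i] * mean(abs(centers[i] - centers[-i])) / intra
  total
}

#' Cluster-validity fitness maximized by the swarm segmenters
#'
#' Pixels are assigned to their nearest center; the fitness is the
#' occupancy-weighted separation over the worst within-cluster scatter,
#' \deqn{f(v) = \sum_i \frac{n_i}{n} \, \mathrm{inter}_i \; / \;
#'   \max_j \mathrm{intra}_j,}
#' summed over nonempty clusters, where \eqn{\mathrm{inter}_i} is the mean
#' distance from center i to the other centers, \eqn{n_i/n} the fraction of
#' pixels in cluster i, and \eqn{\mathrm{intra}_j} the mean absolute
#' distance of cluster j's members to its center (the maximum over nonempty
#' clusters, floored at 1e-9, is the shared denominator). Empty clusters
#' contribute 0. Large values mean well-separated, tight clusters.
#'
#' The weighting matters on continuous CT intensities: a per-cluster
#' denominator would let a handful of coincident extreme pixels produce an
#' unbounded ratio, and unweighted separation would reward pushing a center
#' to the intensity bounds; tying each cluster's separation term to the
#' pixel mass it explains and its compactness to the worst cluster makes
#' the maximum sit on the intensity modes.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param centers Numeric vector of k >= 2 candidate centers.
#' @param bins Histogram resolution (0 = exact per-pixel evaluation).
#' @return Scalar fitness.
#' @export
cluster_fitness <- function(img, centers, bins = 0L) {
  check_image(img)
  if (length(centers) < 2L) stop_param("at least 2 centers required")
  s <- fitness_support(img, as.integer(bins))
  cluster_fitness_vw(s$values, s$weights, centers)
}

new_swarm_state <- function(positions, velocities, fitness, gc = FALSE,
                            rho = 1) {
  gi <- which.max(fitness)
  st <- list(positions = positions, velocities = velocities,
             fitness = fitness,
             pbest_pos = positions, pbest_fit = fitness,
             gbest_pos = positions[gi, ], gbest_fit = fitness[gi],
             t = 0L, draws = NULL)
  if (gc) {
    st$rho <- rho
    st$successes <- 0L
    st$failures <- 0L
    st$tau <- gi
    class(st) <- c("gcpso_state", "swarm_state")
  } else {
    class(st) <- "swarm_state"
  }
  st
}

draw_inertia <- function(config) {
  switch(config$w_mode,
         none = 1,                          # plain update keeps v(t) as is
         constant = config$w,
         random = 0.5 + runif(1) / 2)
}

# Shared machinery: velocity/position update for all particles, then
# book-keeping of personal and global bests (strict improvement).
step_core <- function(state, config, fitness_fn, w, tau_override = NULL) {
  n <- nrow(state$positions); k <- ncol(state$positions)
  r1 <- matrix(runif(n * k), n, k)
  r2 <- matrix(runif(n * k), n, k)
  gb <- matrix(state$gbest_pos, n, k, byrow = TRUE)
  v <- w * state$velocities +
    config$c1 * r1 * (state$pbest_pos - state$positions) +
    config$c2 * r2 * (gb - state$positions)
  draws <- list(w = w, r1 = r1, r2 = r2)
  if (!is.null(tau_override)) {
    i <- tau_override$tau
    r_tau <- runif(k)
    v[i, ] <- -state$positions[i, ] + state$gbest_pos +
      w * state$velocities[i, ] + tau_override$rho * (1 - 2 * r_tau)
    draws$r_tau <- r_tau
  }
  v <- pmin(pmax(v, -config$v_max), config$v_max)
  x <- state$positions + v
  x <- pmin(pmax(x, config$bounds[1L]), config$bounds[2L])
  fit <- vapply(seq_len(n), function(i) fitness_fn(x[i, ]), numeric(1))
  improved <- fit > state$pbest_fit
  state$pbest_pos[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  gi <- which.max(state$pbest_fit)
  state$positions <- x
  state$velocities <- v
  state$fitness <- fit
  state$gbest_pos <- state$pbest_pos[gi, ]
  state$gbest_fit <- state$pbest_fit[gi]
  state$t <- state$t + 1L
  state$draws <- draws
  state
}

#' One iteration of plain PSO
#'
#' Velocity update \eqn{v \leftarrow v + c_1 r_1 (pbest - x) + c_2 r_2
#' (gbest - x)} with fresh per-particle, per-dimension uniform draws, clamped
#' to `v_max`; positions advance by the velocity and are clipped to the
#' bounds; personal and global bests update on strict improvement.
#'
#' @param state A `swarm_state`.
#' @param config A [swarm_config()].
#' @param fitness_fn Function mapping a center vector to a scalar fitness.
#' @return Updated `swarm_state` (the random draws used are kept in
#'   `$draws` for replay).
#' @export
pso_step <- function(state, config, fitness_fn) {
  step_core(state, config, fitness_fn, w = 1)
}

#' One iteration of inertia-weighted PSO
#'
#' As [pso_step()] but the previous velocity is damped by the inertia weight
#' `w`: constant (default 0.7) or redrawn once per iteration as
#' `0.5 + U(0,1)/2` in random mode.
#'
#' @inheritParams pso_step
#' @export
iwpso_step <- function(state, config, fitness_fn) {
  if (config$w_mode == "none")
    stop_param("iwpso_step requires w_mode 'constant' or 'random'")
  step_core(state, config, fitness_fn, w = draw_inertia(config))
}

#' Search-radius update for guaranteed-convergence PSO
#'
#' The radius doubles (by `rho_expand`) after more than `sc` consecutive
#' successes, shrinks (by `rho_contract`) after more than `fc` consecutive
#' failures, and is unchanged otherwise.
#'
#' @param rho Current positive radius.
#' @param success_count,failure_count Consecutive success / failure counts;
#'   at most one may be nonzero.
#' @param config A [swarm_config()] supplying `sc`, `fc`, `rho_expand`,
#'   `rho_contract`.
#' @return Updated radius.
#' @export
update_rho <- function(rho, success_count, failure_count, config) {
  if (success_count > 0 && failure_count > 0)
    stop_param("at most one of success_count and failure_count may be nonzero")
  if (success_count > config$sc) rho * config$rho_expand
  else if (failure_count > config$fc) rho * config$rho_contract
  else rho
}

#' One iteration of guaranteed-convergence PSO
#'
#' All particles except the current global-best holder move as in
#' [iwpso_step()]. The best particle instead performs a guarded local search
#' around the global best: its new position is
#' \eqn{gbest + w v + \rho (1 - 2r)} per dimension with fresh
#' \eqn{r \sim U(0,1)}, so it never strays from a shrinking box around the
#' best known solution. After evaluation, a strict global-best improvement
#' counts as a success (resetting failures) and anything else as a failure
#' (resetting successes); the radius then updates via [update_rho()] and the
#' best-holder index is re-selected.
#'
#' @param state A `gcpso_state` (see [swarm_segment()]).
#' @inheritParams pso_step
#' @export
gcpso_step <- function(state, config, fitness_fn) {
  if (!inherits(state, "gcpso_state"))
    stop_param("state must be a gcpso_state")
  w <- if (config$w_mode == "none") 1 else draw_inertia(config)
  prev_gbest <- state$gbest_fit
  state <- step_core(state, config, fitness_fn, w,
                     tau_override = list(tau = state$tau, rho = state$rho))
  if (state$gbest_fit > prev_gbest) {
    state$successes <- state$successes + 1L
    state$failures <- 0L
  } else {
    state$failures <- state$failures + 1L
    state$successes <- 0L
  }
  state$draws$success <- state$gbest_fit > prev_gbest
  state$rho <- update_rho(state$rho, state$successes, state$failures, config)
  state$tau <- which.max(state$pbest_fit)
  state
}

#' Segment an image with a particle swarm over cluster centers
#'
#' Runs the selected swarm variant over k-dimensional center vectors,
#' maximizing [cluster_fitness()]. Particles start uniformly in the bounds
#' with zero velocity; iteration stops at `max_iter` or after `patience`
#' iterations without global-best improvement. The global-best center vector
#' is returned as a `cluster_model` (centers sorted ascending, nearest-center
#' labels, squared-distance objective) together with the per-iteration
#' global-best fitness trace and, for GCPSO, the radius and counter traces.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param variant `"pso"`, `"iwpso"` or `"gcpso"`.
#' @param k Number of clusters (>= 2).
#' @param config A [swarm_config()]; its `seed` drives all randomness.
#' @return A `cluster_model`; swarm-specific fields: `fitness` (global-best
#'   fitness), `fitness_trace`, and for GCPSO `rho_trace`, `success_trace`
#'   (logical), `successes_trace`, `failures_trace`.
#' @export
swarm_segment <- function(img, variant = c("gcpso", "pso", "iwpso"),
                          k = 3L, config = swarm_config()) {
  variant <- match.arg(variant)
  check_image(img)
  if (length(k) != 1L || k < 2) stop_param("k must be an integer >= 2")
  k <- as.integer(k)
  if (variant %in% c("iwpso", "gcpso") && config$w_mode == "none")
    stop_param(variant, " requires an inertia mode")
  s <- fitness_support(img, config$fitness_bins)
  fitness_fn <- function(centers) cluster_fitness_vw(s$values, s$weights,
                                                     centers)
  gc <- variant == "gcpso"
  rho0 <- config$rho0 * diff(config$bounds)
  step_fn <- switch(variant, pso = pso_step, iwpso = iwpso_step,
                    gcpso = gcpso_step)
  n <- config$n_particles
  run_once <- function(run_seed) with_seed(run_seed, {
    x0 <- matrix(runif(n * k, config$bounds[1L], config$bounds[2L]), n, k)
    f0 <- vapply(seq_len(n), function(i) fitness_fn(x0[i, ]), numeric(1))
    state <- new_swarm_state(x0, matrix(0, n, k), f0, gc = gc, rho = rho0)
    fit_trace <- numeric(config$max_iter)
    rho_trace <- numeric(config$max_iter)
    succ_trace <- logical(config$max_iter)
    s_cnt <- integer(config$max_iter)
    f_cnt <- integer(config$max_iter)
    stale <- 0L
    t <- 0L
    while (t < config$max_iter) {
      t <- t + 1L
      prev <- state$gbest_fit
      state <- step_fn(state, config, fitness_fn)
      fit_trace[t] <- state$gbest_fit
      if (gc) {
        rho_trace[t] <- state$rho
        succ_trace[t] <- isTRUE(state$draws$success)
        s_cnt[t] <- state$successes
        f_cnt[t] <- state$failures
      }
      stale <- if (state$gbest_fit > prev) 0L else stale + 1L
      if (stale >= config$patience) break
    }
    list(state = state, n_iter = t, fit_trace = fit_trace[seq_len(t)],
         rho_trace = rho_trace[seq_len(t)], succ_trace = succ_trace[seq_len(t)],
         s_cnt = s_cnt[seq_len(t)], f_cnt = f_cnt[seq_len(t)],
         converged = t < config$max_iter)
  })
  res <- NULL
  for (r in seq_len(config$restarts)) {
    cand <- run_once(config$seed + 1000L * (r - 1L))
    if (is.null(res) || cand$state$gbest_fit > res$state$gbest_fit) res <- cand
  }
  centers <- res$state$gbest_pos
  extra <- list(fitness = res$state$gbest_fit, fitness_trace = res$fit_trace,
                variant = variant)
  if (gc) {
    extra$rho_trace <- res$rho_trace
    extra$success_trace <- res$succ_trace
    extra$successes_trace <- res$s_cnt
    extra$failures_trace <- res$f_cnt
  }
  new_cluster_model(variant, img, centers, objective_j(img, centers),
                    numeric(0), res$n_iter, res$converged, extra = extra)
}
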