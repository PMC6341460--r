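test_that("validity fitness matches hand arithmetic and direct oracle", {
  # pixels {0, 0.5, 1}, centers {0.25, 0.75}: cluster 1 = {0, 0.5} (the tie
  # at 0.5 breaks to the lower index), cluster 2 = {1}; every member sits
  # 0.25 from its center so the worst scatter is 0.25, the centers are 0.5
  # apart, and the occupancy weights are 2/3 and 1/3:
  # (2/3 * 0.5 + 1/3 * 0.5) / 0.25 = 2.
  img <- matrix(c(0, 0.5, 1, 0, 0.5, 1), 2, 3)
  expect_equal(cluster_fitness(img, c(0.25, 0.75)), 2)
  expect_equal(fitness_oracle(c(0, 0.5, 1), c(0.25, 0.75)), 2)

  for (s in 1:20) {
    px <- withr::with_seed(s, runif(30))
    ctr <- withr::with_seed(s + 200, runif(3))
    img <- matrix(px, 5, 6)
    expect_equal(cluster_fitness(img, ctr), fitness_oracle(px, ctr))
  }
})

test_that("fitness is permutation invariant and floors tight clusters", {
  img <- withr::with_seed(2, matrix(runif(64), 8, 8))
  ctr <- c(0.2, 0.55, 0.9)
  f <- cluster_fitness(img, ctr)
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(cluster_fitness(img, ctr[p]), f)

  # point masses exactly under their centers: scatter hits the 1e-9 floor
  pm <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_gt(cluster_fitness(pm, c(0, 1)), 1e8)

  # an empty cluster contributes nothing
  one <- matrix(0.1, 2, 2)
  expect_equal(cluster_fitness(one, c(0.5, 0.9)), 1)
  expect_error(cluster_fitness(one, 0.5), "2 centers")
})

test_that("a particle sitting on both bests with zero velocity stays put", {
  cfg <- swarm_config(seed = 1)
  fit_fn <- function(ctr) -sum((ctr - 0.7)^2)
  pos <- rbind(c(0.7, 0.7), c(0.2, 0.9))
  st <- manual_state(pos, matrix(0, 2, 2), fit_fn)
  st2 <- withr::with_seed(1, pso_step(st, cfg, fit_fn))
  expect_equal(st2$positions[1, ], c(0.7, 0.7))
  expect_equal(st2$velocities[1, ], c(0, 0))
})

test_that("with zero acceleration the update is pure drift", {
  cfg <- swarm_config(c1 = 0, c2 = 0, seed = 1)
  fit_fn <- function(ctr) 0            # constant: bests never move
  st <- manual_state(rbind(c(0.3, 0.4), c(0.5, 0.6)),
                     matrix(0.1, 2, 2), fit_fn)
  st2 <- withr::with_seed(1, pso_step(st, cfg, fit_fn))
  expect_equal(st2$positions, st$positions + 0.1)

  # inertia 0.7 decays a free velocity geometrically: 0.07, 0.049, 0.0343
  sti <- manual_state(matrix(0.5, 1, 2), matrix(0.1, 1, 2), fit_fn)
  v <- c()
  for (i in 1:3) {
    sti <- withr::with_seed(i, iwpso_step(sti, cfg, fit_fn))
    v <- c(v, sti$velocities[1, 1])
  }
  expect_equal(v, c(0.07, 0.049, 0.0343))
})

test_that("one step replays exactly from the logged random draws", {
  cfg <- swarm_config(seed = 1)
  img <- two_level_image(8)
  fit_fn <- function(ctr) cluster_fitness(img, ctr)
  st <- manual_state(withr::with_seed(5, matrix(runif(6), 3, 2)),
                     matrix(0.05, 3, 2), fit_fn)
  st2 <- withr::with_seed(6, iwpso_step(st, cfg, fit_fn))
  d <- st2$draws
  v_exp <- d$w * st$velocities +
    cfg$c1 * d$r1 * (st$pbest_pos - st$positions) +
    cfg$c2 * d$r2 * (matrix(st$gbest_pos, 3, 2, byrow = TRUE) -
                       st$positions)
  v_exp <- pmin(pmax(v_exp, -cfg$v_max), cfg$v_max)
  x_exp <- pmin(pmax(st$positions + v_exp, 0), 1)
  expect_equal(st2$velocities, v_exp)
  expect_equal(st2$positions, x_exp)
})

test_that("radius update follows the success/failure thresholds", {
  cfg <- swarm_config(seed = 1)                  # sc = 15, fc = 5
  expect_equal(update_rho(1.0, 16, 0, cfg), 2.0)
  expect_equal(update_rho(1.0, 3, 0, cfg), 1.0)
  expect_equal(update_rho(1.0, 0, 6, cfg), 0.5)
  expect_equal(update_rho(1.0, 15, 0, cfg), 1.0) # strict thresholds
  expect_equal(update_rho(1.0, 0, 5, cfg), 1.0)
  expect_error(update_rho(1.0, 2, 3, cfg), "one of")
})

test_that("the best particle's guarded step lands on gbest as rho -> 0", {
  cfg <- swarm_config(seed = 1)
  fit_fn <- function(ctr) -sum((ctr - 0.65)^2)
  pos <- rbind(c(0.6, 0.6), c(0.3, 0.3))        # particle 1 holds gbest
  st <- manual_state(pos, matrix(0, 2, 2), fit_fn, gc = TRUE, rho = 1e-12)
  st2 <- withr::with_seed(2, gcpso_step(st, cfg, fit_fn))
  expect_equal(st2$positions[st$tau, ], st$gbest_pos, tolerance = 1e-9)
  # replay the guarded velocity from the logged draws
  d <- st2$draws
  v_exp <- -st$positions[1, ] + st$gbest_pos + d$w * st$velocities[1, ] +
    1e-12 * (1 - 2 * d$r_tau)
  expect_equal(st2$velocities[1, ], v_exp)
})

test_that("gcpso state keeps its invariants across many steps", {
  cfg <- swarm_config(seed = 1)
  img <- two_level_image(12)
  fit_fn <- function(ctr) cluster_fitness(img, ctr)
  st <- manual_state(withr::with_seed(9, matrix(runif(8), 4, 2)),
                     matrix(0, 4, 2), fit_fn, gc = TRUE, rho = 1)
  rho_seen <- c(); succ <- c()
  withr::with_seed(10, for (t in 1:40) {
    prev_fit <- st$gbest_fit
    st <- gcpso_step(st, cfg, fit_fn)
    expect_true(all(st$positions >= 0 & st$positions <= 1))
    expect_true(all(abs(st$velocities) <= cfg$v_max + 1e-12))
    expect_true(st$rho > 0)
    expect_true(st$successes == 0 || st$failures == 0)
    expect_gte(st$gbest_fit, prev_fit)
    rho_seen <- c(rho_seen, st$rho)
    succ <- c(succ, st$draws$success)
  })
  # replay the radius trace from the logged success/failure events
  rho <- 1; s <- 0L; f <- 0L; expected <- c()
  for (ok in succ) {
    if (ok) { s <- s + 1L; f <- 0L } else { f <- f + 1L; s <- 0L }
    rho <- update_rho(rho, s, f, cfg)
    expected <- c(expected, rho)
  }
  expect_equal(rho_seen, expected)
})

test_that("all variants recover well-separated class intensities", {
  img <- two_level_image(16, 0.2, 0.8)
  for (v in c("pso", "iwpso", "gcpso")) {
    m <- swarm_segment(img, v, k = 2,
                       config = swarm_config(seed = 4, restarts = 2))
    expect_lt(max(abs(m$centers - c(0.2, 0.8))), 0.05)
    expect_true(all(diff(m$fitness_trace) >= 0))
  }
})

test_that("swarm segmentation is deterministic under a fixed seed", {
  img <- withr::with_seed(3, two_level_image(12) +
                            matrix(runif(144, 0, 0.05), 12, 12))
  a <- swarm_segment(img, "gcpso", 2,
                     swarm_config(seed = 7, restarts = 2, max_iter = 40))
  b <- swarm_segment(img, "gcpso", 2,
                     swarm_config(seed = 7, restarts = 2, max_iter = 40))
  expect_identical(a$centers, b$centers)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(a$labels, b$labels)
})

test_that("histogram-based fitness evaluation matches exact evaluation", {
  ph <- make_phantom(phantom_spec(height = 40L, width = 40L,
                                  lung_ellipses = list(
                                    list(center = c(20, 20),
                                         axes = c(14, 12), level = 0.35)),
                                  tumor_disc = list(center = c(18, 20),
                                                    radius = 4, level = 0.85),
                                  speckle_var = 0.02, seed = 2))
  mh <- swarm_segment(ph$image, "gcpso", 3,
                      swarm_config(seed = 2, restarts = 2, max_iter = 50,
                                   fitness_bins = 256L))
  me <- swarm_segment(ph$image, "gcpso", 3,
                      swarm_config(seed = 2, restarts = 2, max_iter = 50,
                                   fitness_bins = 0L))
  expect_lt(max(abs(mh$centers - me$centers)), 0.02)
})
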