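test_that("clustering objective equals the per-pixel nearest-distance sum", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(objective_j(img, c(0, 1)), 0)
  expect_equal(objective_j(img, 0.5), 4 * 0.25)
  for (s in 1:20) {
    img <- withr::with_seed(s, matrix(runif(16), 4, 4))
    ctr <- withr::with_seed(s + 100, runif(2))
    brute <- sum(apply(abs(outer(as.vector(img), ctr, "-"))^2, 1, min))
    expect_equal(objective_j(img, ctr), brute)
  }
  expect_error(objective_j(img, numeric(0)), "nonempty")
})

test_that("k-means recovers separable groups and canonical ordering", {
  img <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3)
  m <- kmeans_segment(img, 2, seed = 1)
  expect_equal(m$centers, c(0, 1))
  expect_equal(m$objective, 0)
  expect_true(all(m$labels[img == 0] == 1) && all(m$labels[img == 1] == 2))

  img <- matrix(c(0, 0.1, 0.9, 1), 2, 2)
  m <- kmeans_segment(img, 2, seed = 1)
  expect_equal(m$centers, c(0.05, 0.95))
  expect_equal(m$objective, exhaustive_k2_optimum(img))
})

test_that("k-means objective trace is nonincreasing on every seeded run", {
  for (s in 1:10) {
    img <- withr::with_seed(s, matrix(runif(144), 12, 12))
    m <- kmeans_segment(img, 3, seed = s, restarts = 1)
    expect_true(all(diff(m$objective_trace) <= 1e-12))
    expect_true(all(tabulate(m$labels, m$k) > 0))   # no empty clusters
  }
})

test_that("best-of-restarts attains the exhaustive two-cluster optimum", {
  for (s in 1:5) {
    vals <- withr::with_seed(s, sort(runif(7)))
    img <- withr::with_seed(s + 50,
                            matrix(sample(vals, 36, replace = TRUE), 6, 6))
    if (length(unique(as.vector(img))) < 3) next
    m <- kmeans_segment(img, 2, seed = s, restarts = 10)
    expect_equal(m$objective, exhaustive_k2_optimum(img), tolerance = 1e-10)
  }
})

test_that("k-means matches the reference implementation's optimum", {
  img <- withr::with_seed(8, matrix(runif(144), 12, 12))
  ours <- kmeans_segment(img, 3, seed = 8)
  ref <- withr::with_seed(8,
    stats::kmeans(as.vector(img), centers = 3, nstart = 10))
  expect_lte(ours$objective, ref$tot.withinss * (1 + 1e-10))
})

test_that("k-median centers are member medians at convergence", {
  for (s in 1:5) {
    img <- withr::with_seed(s, matrix(runif(100), 10, 10))
    m <- kmedian_segment(img, 3, seed = s)
    for (j in seq_len(m$k)) {
      members <- img[m$labels == j]
      expect_equal(m$centers[j], median(members))
    }
    expect_true(all(diff(m$objective_trace) <= 1e-12))
  }
})

test_that("k-median resists outliers where the mean does not", {
  # members {0.1, 0.2, 0.9}: the median center is 0.2, the mean 0.4
  expect_equal(swarmseg:::weighted_median(c(0.1, 0.2, 0.9), c(1, 1, 1)), 0.2)
  expect_equal(swarmseg:::weighted_median(c(0, 1), c(3, 1)), 0)
  expect_equal(swarmseg:::weighted_median(c(0, 1), c(1, 1)), 0.5)
})

test_that("degenerate inputs are rejected", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_error(kmeans_segment(img, 3, seed = 1), "distinct")
  expect_error(kmeans_segment(img, 1, seed = 1), "k must be")
})
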