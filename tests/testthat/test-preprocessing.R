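test_that("median filter matches the sort-and-pick oracle pixelwise", {
  for (s in 1:25) {
    img <- withr::with_seed(s, matrix(runif(81), 9, 9))
    expect_equal(median_filter(img, 3), median_filter_oracle(img, 3))
  }
  img <- withr::with_seed(99, matrix(runif(81), 9, 9))
  expect_equal(median_filter(img, 5), median_filter_oracle(img, 5))
})

test_that("median filter removes a lone impulse and fixes constants", {
  expect_equal(median_filter(matrix(0.4, 5, 5), 3), matrix(0.4, 5, 5))
  img <- matrix(0, 3, 3); img[2, 2] <- 1
  expect_equal(median_filter(img, 3), matrix(0, 3, 3))
  # output never leaves the input's range
  img <- withr::with_seed(1, matrix(runif(49), 7, 7))
  out <- median_filter(img, 3)
  expect_true(min(out) >= min(img) && max(out) <= max(img))
})

test_that("average filter matches the window-mean oracle", {
  img <- matrix(0, 3, 3); img[2, 2] <- 0.9
  expect_equal(average_filter(img, 3)[2, 2], 0.1)
  for (s in 1:10) {
    img <- withr::with_seed(s, matrix(runif(63), 9, 7))
    expect_equal(average_filter(img, 3), average_filter_oracle(img, 3))
  }
})

test_that("windowed filters validate their window", {
  img <- matrix(0.5, 4, 4)
  expect_error(median_filter(img, 4), "odd")
  expect_error(average_filter(img, -3), "odd")
  expect_error(adaptive_median_filter(img, 5, 3), "smax")
})

test_that("adaptive median passes smooth images through unchanged", {
  # axis-aligned gradient: no pixel is a window extreme whose value differs
  # from the window median
  img <- matrix(rep(seq(0, 1, length.out = 12), each = 8), 8, 12)
  expect_equal(adaptive_median_filter(img, 3, 7), img)
})

test_that("adaptive median restores impulse corruption exactly", {
  base <- matrix(0.5, 24, 24)
  noisy <- add_impulses(base, 0.1, seed = 3)
  restored <- adaptive_median_filter(noisy, 3, 7)
  interior <- restored[2:23, 2:23]
  expect_true(all(interior == 0.5))
  # single impulse on a constant image
  img <- matrix(0.3, 7, 7); img[4, 4] <- 1
  expect_equal(adaptive_median_filter(img, 3, 7), matrix(0.3, 7, 7))
})

test_that("global equalization maps pixels to cumulative mass", {
  img <- matrix(0.2, 10, 10)
  img[1:25] <- 0.8                     # 25% bright, 75% dark
  out <- global_hist_equalize(img, 256)
  expect_equal(unique(out[img == 0.2]), 0.75)
  expect_equal(unique(out[img == 0.8]), 1.0)
})

test_that("equalization preserves the rank order of intensities", {
  img <- withr::with_seed(4, matrix(runif(400), 20, 20))
  out <- global_hist_equalize(img, 64)
  o <- order(as.vector(img))
  expect_true(all(diff(out[o]) >= 0))
  # a uniform intensity spread is (nearly) a fixed point
  img <- matrix(seq(0, 1, length.out = 256), 16, 16)
  out <- global_hist_equalize(img, 256)
  expect_lt(max(abs(out - img)), 1 / 256 + 1e-12)
})

test_that("single-tile unclipped CLAHE equals global equalization", {
  img <- withr::with_seed(5, matrix(runif(300), 15, 20))
  expect_equal(clahe(img, tiles = c(1, 1), clip = 1),
               global_hist_equalize(img, 256))
})

test_that("CLAHE maps constants to constants and raises contrast", {
  out <- clahe(matrix(0.4, 16, 16), c(4, 4), 0.5)
  expect_equal(length(unique(as.vector(out))), 1L)
  # low-contrast phantom: output spread should not shrink
  ph <- make_phantom(phantom_spec(speckle_var = 0.001, seed = 11))
  lowc <- 0.4 + ph$image * 0.2          # squeeze into [0.4, 0.6]
  out <- clahe(lowc, c(8, 8), 0.05)
  expect_gte(sd(as.vector(out)), sd(as.vector(lowc)))
  expect_true(all(out >= 0 & out <= 1))
})
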