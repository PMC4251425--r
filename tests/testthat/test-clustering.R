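test_that("density measure matches direct term-by-term evaluation", {
  # single point: only the self-term exp(0) = 1
  expect_equal(density_measure(0, r_a = 0.5), 1.0)
  # two coincident points: both exponents zero
  expect_equal(density_measure(c(0, 0), r_a = 0.5), c(2, 2))
  # 1-D {0, 0.25, 1}: hand-derived sums of the Gaussian terms
  D <- density_measure(c(0, 0.25, 1), r_a = 0.5)
  expect_equal(D[1], 1 + exp(-1) + exp(-16), tolerance = 1e-12)
  expect_equal(D[2], exp(-1) + 1 + exp(-9), tolerance = 1e-12)
  expect_equal(D[3], exp(-16) + exp(-9) + 1, tolerance = 1e-12)
  # bounds: self-term makes every density >= 1, and <= n
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  D <- density_measure(X, r_a = 0.7)
  expect_true(all(D >= 1 - 1e-12) && all(D <= 20))
})

test_that("density measure rejects degenerate input", {
  expect_error(density_measure(numeric(0)), "at least one row")
  expect_error(density_measure(c(0, NA)), "finite")
  expect_error(density_measure(c(0, Inf)), "finite")
  expect_error(density_measure(0, r_a = 0), "positive")
  expect_error(density_measure(0, r_a = -1), "positive")
})

test_that("density revision suppresses the selected center's neighbourhood", {
  x <- c(0, 0.25, 1)
  D <- density_measure(x, r_a = 0.5)
  c_idx <- which.max(D)
  D2 <- revise_density(D, x, c_idx, r_b = 0.8)
  # revised density at the center is exactly zero
  expect_identical(D2[c_idx], 0)
  # matches the naive term-by-term oracle
  expect_equal(D2, naive_revise(D, matrix(x, ncol = 1), c_idx, 0.8),
    tolerance = 1e-12
  )
  # a point at distance 2*r_b changes by exactly D_c * e^{-16}
  x2 <- c(0, 2 * 0.8)
  D <- density_measure(x2, r_a = 0.5)
  D2 <- revise_density(D, x2, 1, r_b = 0.8)
  # the subtraction D - D2 cancels ~7 digits, so compare at 1e-8 relative
  expect_equal(D[2] - D2[2], D[1] * exp(-16), tolerance = 1e-8)
  expect_error(revise_density(D, x2, 5, 0.8), "out of range")
})

test_that("revision never increases any density", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(runif(30 * 2), 30, 2)
    D <- density_measure(X, r_a = 0.4)
    D2 <- revise_density(D, X, which.max(D), r_b = 0.64)
    expect_true(all(D2 <= D + 1e-12))
  }
})

test_that("find_centers selects actual data rows with non-increasing density", {
  set.seed(3)
  X <- matrix(runif(80), 40, 2)
  fc <- find_centers(X, r_a = 0.3, r_b = 0.48, accept_ratio = 0.3)
  expect_true(all(fc$indices %in% seq_len(40)))
  # centers are exact input rows, in original coordinates
  for (i in seq_along(fc$indices)) {
    expect_identical(fc$centers[i, ], X[fc$indices[i], ])
  }
  expect_true(all(diff(fc$densities) <= 1e-12))
  # first center carries the globally maximal initial density
  expect_equal(fc$indices[1], which.max(density_measure(unit_scaled(X), 0.3)))
})

test_that("two tight groups give two centers, ties broken by lowest index", {
  pts <- c(rep(0, 10), rep(1, 10))
  fc <- find_centers(pts, r_a = 0.5, r_b = 0.8, accept_ratio = 0.15)
  expect_setequal(fc$centers[, 1], c(0, 1))
  # both groups tie on density; the lowest row index (value 0) wins first
  expect_identical(fc$centers[1, 1], 0)
  # all points coincident: revision zeroes every density -> one center
  fc1 <- find_centers(rep(3.7, 15))
  expect_length(fc1$indices, 1)
})

test_that("parameter validation enforces the radius relations", {
  expect_error(find_centers(1:5, r_a = 0.5, r_b = 0.4), "exceed")
  expect_error(find_centers(1:5, r_a = 0.5, r_b = 0.9, eta = 1.6), "eta")
  expect_error(find_centers(1:5, accept_ratio = 0), "0, 1")
  expect_error(find_centers(1:5, eta = 0.9), "greater than 1")
  # eta consistent with r_b passes
  expect_silent(find_centers(1:5, r_a = 0.5, r_b = 0.8, eta = 1.6))
})

test_that("tidy() reports one row per center with coordinates", {
  b <- make_blobs(2, n_per = 15, seed = 5)
  fc <- find_centers(b$X, r_a = 0.25, accept_ratio = 0.15)
  td <- tidy(fc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(fc$indices))
  expect_true(all(c("center", "row", "density") %in% names(td)))
})
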