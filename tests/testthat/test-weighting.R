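test_that("a constant non-zero feature gets weight 1 and is left unchanged", {
  d <- tibble::tibble(
    f1 = rep(3.5, 20),
    f2 = c(rnorm(10, 1), rnorm(10, 4)),
    class = factor(rep(c("0", "1"), each = 10))
  )
  w <- scfw_fit(d, "class")
  expect_equal(unname(w$weights[["f1"]]), 1, tolerance = 1e-12)
  out <- predict(w, d)
  expect_equal(out$f1, d$f1)
})

test_that("weights equal the mean-over-center ratio from the clustering oracle", {
  set.seed(8)
  d <- tibble::tibble(
    f1 = c(rnorm(15, 2, 0.5), rnorm(30, 6, 0.5)),
    f2 = c(rnorm(15, 10, 1), rnorm(30, 11, 2)),
    class = factor(rep(c("0", "1"), c(15, 30)))
  )
  w <- scfw_fit(d, "class")
  for (f in c("f1", "f2")) {
    centers <- vapply(
      levels(d$class),
      function(cl) naive_center_1d(d[[f]][d$class == cl]),
      numeric(1)
    )
    expect_equal(unname(w$weights[[f]]), mean(d[[f]]) / mean(centers),
      tolerance = 1e-10
    )
    # reported per-class centers match the oracle too
    got <- w$centers$center[w$centers$feature == f]
    expect_equal(got, unname(centers), tolerance = 1e-10)
  }
})

test_that("applying weights is exact scalar multiplication and invertible", {
  d <- random_table(n = 25, m = 3, seed = 2)
  w <- scfw_fit(d, "class")
  out <- predict(w, d)
  # label column and row order untouched
  expect_identical(out$class, d$class)
  for (f in w$features) {
    expect_equal(out[[f]], d[[f]] * w$weights[[f]], tolerance = 0)
    # divide recovers the input
    expect_equal(out[[f]] / w$weights[[f]], d[[f]], tolerance = 1e-12)
  }
  # matrix interface: weights c(2) on [[1],[3]] -> [[2],[6]]
  w$weights <- c(f1 = 2)
  w$features <- "f1"
  expect_equal(
    predict(w, matrix(c(1, 3), ncol = 1)),
    matrix(c(2, 6), ncol = 1)
  )
})

test_that("column mismatch errors name the expected and missing columns", {
  d <- random_table(n = 15, m = 3, seed = 4)
  w <- scfw_fit(d, "class")
  expect_error(predict(w, d[, c("f1", "class")]), "column mismatch")
  expect_error(predict(w, matrix(0, 2, 2)), "3 features")
})

test_that("permuting feature columns permutes the weights identically", {
  d <- random_table(n = 30, m = 4, seed = 9)
  w1 <- scfw_fit(d, "class")
  perm <- c("f3", "f1", "f4", "f2")
  w2 <- scfw_fit(d[, c(perm, "class")], "class")
  expect_equal(w2$weights[perm], w1$weights[perm], tolerance = 1e-12)
  expect_named(w2$weights, perm)
})

test_that("weights fitted on a training split never read held-out data", {
  d <- random_table(n = 40, m = 3, seed = 6)
  train <- d[1:30, ]
  w1 <- scfw_fit(train, "class")
  # corrupt the held-out rows wildly; the transform must be unchanged
  held <- d[31:40, ]
  held[, 1:3] <- held[, 1:3] * 1e6 + 123
  w2 <- scfw_fit(train, "class")
  expect_identical(w1$weights, w2$weights)
  # and applying to the corrupted split is still plain multiplication
  out <- predict(w1, held)
  expect_equal(out$f2, held$f2 * w1$weights[["f2"]])
})

test_that("an exactly-zero center leaves the feature unweighted with a warning", {
  d <- tibble::tibble(
    f1 = rep(0, 20), # both class centers are exactly 0
    f2 = c(rnorm(10, 5), rnorm(10, 8)),
    class = factor(rep(c("0", "1"), each = 10))
  )
  expect_warning(w <- scfw_fit(d, "class"), "weight set to 1")
  expect_equal(unname(w$weights[["f1"]]), 1)
})

test_that("pooled mode clusters without labels, one center per class count", {
  set.seed(12)
  d <- tibble::tibble(f1 = c(rnorm(25, 0, 0.2), rnorm(25, 5, 0.2)))
  w <- scfw_fit(d, label_col = NULL, mode = "pooled", n_classes = 2)
  centers <- sort(w$centers$center)
  expect_equal(centers[1], 0, tolerance = 0.3)
  expect_equal(centers[2], 5, tolerance = 0.3)
  expect_error(scfw_fit(d, label_col = NULL), "pooled")
})

test_that("summed Fisher score is preserved under weighting", {
  d <- synth_benchmark(seed = 4)
  before <- sum(fisher_score(d, "class")$fisher)
  after <- sum(fisher_score(predict(scfw_fit(d, "class"), d), "class")$fisher)
  expect_gte(after, before - 1e-8 * abs(before))
})

test_that("tidy() lays out feature, per-class centers and weight", {
  d <- random_table(n = 20, m = 2, seed = 3)
  td <- tidy(scfw_fit(d, "class"))
  expect_named(td, c("feature", "center_0", "center_1", "mean", "weight"))
  expect_equal(nrow(td), 2)
})
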