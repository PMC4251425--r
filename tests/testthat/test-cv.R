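test_that("the seeded partition is valid and balanced", {
  for (s in 1:5) {
    f <- scfwkelm:::make_folds(47, 10, seed = s)
    expect_length(f, 47)
    sizes <- table(f)
    expect_equal(length(sizes), 10)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(scfwkelm:::make_folds(5, 10, 1), "exceeds")
  expect_error(scfwkelm:::make_folds(5, 1, 1), "at least 2")
})

test_that("repeated CV is deterministic in its seed and covers every sample", {
  d <- synth_two_class(n_per_class = c(15, 30), seed = 3)
  spec <- kelm_spec("rbf", log2C = 5, log2gamma = -5)
  r1 <- kfold_cv(d, "class", spec, k = 5, repeats = 2, seed = 11)
  r2 <- kfold_cv(d, "class", spec, k = 5, repeats = 2, seed = 11)
  expect_equal(r1$folds, r2$folds)
  expect_equal(r1$summary, r2$summary)
  r3 <- kfold_cv(d, "class", spec, k = 5, repeats = 2, seed = 12)
  expect_false(isTRUE(all.equal(r1$folds, r3$folds)))
  # every sample is held out exactly once per repeat
  per_repeat <- tapply(r1$folds$n_test, r1$folds$repeat_id, sum)
  expect_true(all(per_repeat == nrow(d)))
})

test_that("aggregates agree with a hand average of the folds", {
  d <- synth_two_class(n_per_class = c(12, 24), seed = 5)
  r <- kfold_cv(d, "class", kelm_spec("linear", C = 1), k = 4, repeats = 2, seed = 2)
  acc_row <- r$summary[r$summary$metric == "accuracy", ]
  expect_equal(acc_row$mean, mean(r$folds$accuracy))
  expect_equal(acc_row$sd, sd(r$folds$accuracy))
  expect_equal(acc_row$max, max(r$folds$accuracy))
  expect_equal(acc_row$min, min(r$folds$accuracy))
  g <- glance(r)
  expect_equal(g$accuracy, acc_row$mean)
})

test_that("stratified folds keep both classes in every training split", {
  d <- synth_two_class(n_per_class = c(8, 40), seed = 7)
  r <- kfold_cv(d, "class", kelm_spec("rbf", log2C = 0, log2gamma = -3),
    k = 4, repeats = 2, seed = 9, stratified = TRUE
  )
  # with 8 minority samples and k = 4 every fold holds exactly 2 of them
  expect_true(all(r$folds$tp + r$folds$fn > 0))
  expect_true(all(r$folds$fp + r$folds$tn > 0))
})

test_that("fold-level weighting refits the transform inside each split", {
  d <- synth_benchmark(seed = 6)
  r_fold <- kfold_cv(d, "class", kelm_spec("rbf", log2C = 5, log2gamma = -10),
    k = 5, repeats = 1, seed = 21, weighting = "fold"
  )
  r_whole <- kfold_cv(d, "class", kelm_spec("rbf", log2C = 5, log2gamma = -10),
    k = 5, repeats = 1, seed = 21, weighting = "whole"
  )
  # whole-table weighting stores its transform; fold mode cannot
  expect_null(r_fold$transform)
  expect_s3_class(r_whole$transform, "scfw")
  # identical partitions, so test-set sizes match fold for fold
  expect_equal(r_fold$folds$n_test, r_whole$folds$n_test)
})

test_that("whole-table weighting equals weighting by hand then running raw CV", {
  d <- synth_benchmark(seed = 8)
  spec <- kelm_spec("rbf", log2C = 5, log2gamma = -10)
  r1 <- kfold_cv(d, "class", spec, k = 5, repeats = 1, seed = 4, weighting = "whole")
  weighted <- predict(scfw_fit(d, "class"), d)
  r2 <- kfold_cv(weighted, "class", spec, k = 5, repeats = 1, seed = 4)
  expect_equal(r1$folds$accuracy, r2$folds$accuracy)
})

test_that("ELM and kNN run inside the harness", {
  d <- make_separable(n_per_class = c(15, 20), seed = 2)
  r_elm <- kfold_cv(d, "class", elm_spec(hidden = 10), k = 5, repeats = 1, seed = 3)
  expect_gt(r_elm$summary$mean[r_elm$summary$metric == "accuracy"], 80)
  r_knn <- kfold_cv(d, "class", knn_spec(k = 3), k = 5, repeats = 1, seed = 3)
  expect_gt(r_knn$summary$mean[r_knn$summary$metric == "accuracy"], 80)
  # knn yields no continuous score, hence no AUC
  expect_true(all(is.na(r_knn$folds$auc)))
})

test_that("grid search returns the surface argmax with conservative ties", {
  d <- make_separable(n_per_class = c(15, 25), seed = 4)
  g <- kelm_grid_search(d, "class",
    kernel = "rbf", log2C = c(0, 5, 10),
    log2gamma = c(-10, -5, 0), k = 3, seed = 6
  )
  expect_equal(nrow(g$surface), 9)
  expect_equal(g$best_accuracy, max(g$surface$accuracy))
  firsts <- which(g$surface$accuracy == g$best_accuracy)[1]
  expect_equal(g$surface$log2C[firsts], g$best_log2C)
  expect_equal(g$surface$log2gamma[firsts], g$best_log2gamma)
  # separable data reaches 100% somewhere on the grid
  expect_equal(g$best_accuracy, 100)
  # single-cell grid returns that cell
  g1 <- kelm_grid_search(d, "class",
    kernel = "rbf", log2C = 5, log2gamma = -5,
    k = 3, seed = 6
  )
  expect_equal(nrow(g1$surface), 1)
  expect_equal(g1$best_log2C, 5)
  # linear kernel ignores gamma: one column of cells
  gl <- kelm_grid_search(d, "class", kernel = "linear", log2C = c(0, 5), k = 3, seed = 6)
  expect_equal(nrow(gl$surface), 2)
  expect_true(all(is.na(gl$surface$log2gamma)))
})

test_that("autoplot methods return ggplot objects", {
  d <- make_separable(n_per_class = c(10, 15), seed = 5)
  r <- kfold_cv(d, "class", kelm_spec("linear", C = 1), k = 3, repeats = 1, seed = 1)
  expect_s3_class(autoplot(r), "ggplot")
  g <- kelm_grid_search(d, "class", log2C = c(0, 5), log2gamma = c(-5, 0), k = 3, seed = 1)
  expect_s3_class(autoplot(g), "ggplot")
  w <- scfw_fit(d, "class")
  expect_s3_class(autoplot(w), "ggplot")
})
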