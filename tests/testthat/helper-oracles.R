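# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's vectorized code paths.

naive_density <- function(X, r_a) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      s <- s + exp(-sum((X[i, ] - X[j, ])^2) / (r_a / 2)^2)
    }
    D[i] <- s
  }
  D
}

naive_revise <- function(D, X, center, r_b) {
  X <- as.matrix(X)
  out <- numeric(length(D))
  for (i in seq_along(D)) {
    out[i] <- D[i] - D[center] * exp(-sum((X[i, ] - X[center, ])^2) / (r_b / 2)^2)
  }
  out[center] <- 0
  out
}

# 1-D subtractive-clustering center by exhaustive evaluation: min-max
# scale, pick the max-density value, return it in original units.
naive_center_1d <- function(values, r_a = 0.5) {
  lo <- min(values)
  span <- max(values) - lo
  v <- if (span == 0) rep(0, length(values)) else (values - lo) / span
  values[which.max(naive_density(matrix(v, ncol = 1), r_a))]
}

# Ridge-regression decision scores via the primal normal equations.
ridge_scores <- function(X_train, T_mat, X_new, C) {
  beta <- solve(
    crossprod(X_train) + diag(ncol(X_train)) / C,
    crossprod(X_train, T_mat)
  )
  X_new %*% beta
}

# k-NN by exhaustive all-pairs distances, nearest-class tie-break.
brute_knn <- function(X_train, y_train, X_new, k) {
  y_train <- as.character(y_train)
  out <- character(nrow(X_new))
  for (i in seq_len(nrow(X_new))) {
    d <- apply(X_train, 1, function(r) sqrt(sum((r - X_new[i, ])^2)))
    ord <- order(d)
    neigh <- y_train[ord[seq_len(k)]]
    counts <- table(neigh)
    tied <- names(counts)[counts == max(counts)]
    out[i] <- if (length(tied) == 1) tied else neigh[neigh %in% tied][1]
  }
  out
}

# Confusion counts by explicit tally.
tally_confusion <- function(truth, est, positive) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == positive) {
      if (est[i] == positive) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (est[i] == positive) fp <- fp + 1 else tn <- tn + 1
    }
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# AUC by all-pairs comparison counting ties as one half.
pairwise_auc <- function(scores, truth, positive) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  100 * s / (length(pos) * length(neg))
}

# Best training accuracy achievable by thresholding any single feature in
# either direction — an exhaustive sweep bounding linear 1-D separability.
best_threshold_accuracy <- function(X, y) {
  y <- as.character(y)
  best <- 0
  for (j in seq_len(ncol(X))) {
    cuts <- sort(unique(X[, j]))
    cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2, cuts[length(cuts)] + 1)
    for (cut in cuts) {
      for (cls in unique(y)) {
        acc <- mean((X[, j] > cut) == (y == cls))
        best <- max(best, acc, 1 - acc)
      }
    }
  }
  100 * best
}
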