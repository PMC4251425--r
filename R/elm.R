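#' Extreme learning machine (random hidden layer)
#'
#' Fits the original single-hidden-layer extreme learning machine: input
#' weights `W` and biases `b` are drawn uniformly on (-1, 1) from a seeded
#' generator and never trained; the hidden activations
#' `H = sigmoid(X W' + b)` are computed once, and the output weights are the
#' minimum-norm least-squares solution \eqn{\beta = H^{+} T} via the
#' Moore-Penrose pseudoinverse (singular values below
#' \eqn{10^{-12}\sigma_{max}} treated as zero). The same seed yields a
#' bit-identical model; the caller's RNG state is left untouched.
#'
#' @inheritParams kelm
#' @param hidden Number of hidden neurons `L`.
#' @param seed Integer seed for the random hidden layer.
#' @return An `elm` model object.
#' @export
elm <- function(data, label_col, hidden = 20, seed = 1) {
  if (!is.numeric(hidden) || length(hidden) != 1 || hidden < 1 ||
    hidden != round(hidden)) {
    abort("`hidden` must be a positive integer")
  }
  fm <- as_feature_matrix(data, label_col)
  if (is.null(fm$y)) abort("`label_col` is required")
  m <- ncol(fm$X)
  rand <- with_local_seed(seed, list(
    W = matrix(runif(hidden * m, -1, 1), hidden, m),
    b = runif(hidden, -1, 1)
  ))
  H <- sigmoid(tcrossprod(fm$X, rand$W) + rep(rand$b, each = nrow(fm$X)))
  T_mat <- signed_targets(fm$y)
  beta <- pinv(H) %*% T_mat

  structure(
    list(
      W = rand$W, b = rand$b, beta = beta,
      hidden = hidden, seed = seed,
      classes = levels(fm$y), label_col = label_col,
      features = fm$features, activation = "sigmoid"
    ),
    class = "elm"
  )
}

#' Predict from an extreme learning machine
#'
#' @inheritParams predict.kelm
#' @param object A fitted [elm()] model.
#' @return As [predict.kelm()].
#' @export
predict.elm <- function(object, newdata, type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  X_new <- newdata_matrix(newdata, object$features)
  H <- sigmoid(tcrossprod(X_new, object$W) + rep(object$b, each = nrow(X_new)))
  finish_prediction(H %*% object$beta, object$classes, type)
}

#' @export
print.elm <- function(x, ...) {
  cat(
    "ELM:", x$hidden, "sigmoid hidden neurons (seed", x$seed, "),",
    length(x$features), "features; classes:",
    paste(x$classes, collapse = ", "), "\n"
  )
  invisible(x)
}

#' k-nearest-neighbour classification
#'
#' Euclidean k-nearest-neighbour majority vote. Ties between classes are
#' broken deterministically toward the class of the nearest neighbour among
#' the tied classes, so results never depend on the RNG.
#'
#' @inheritParams kelm
#' @param newdata Rows to classify.
#' @param k Neighbourhood size, between 1 and the number of training rows.
#' @return A factor of predicted labels for `newdata`.
#' @export
knn_classify <- function(data, label_col, newdata, k = 1) {
  fm <- as_feature_matrix(data, label_col)
  if (is.null(fm$y)) abort("`label_col` is required")
  n <- nrow(fm$X)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
    abort(paste0("`k` must be an integer in [1, ", n, "]"))
  }
  X_new <- newdata_matrix(newdata, fm$features)
  d2 <- cross_dist2(X_new, fm$X)
  classes <- levels(fm$y)
  labels <- apply(d2, 1, function(row) {
    ord <- order(row) # stable: earlier training row wins distance ties
    neigh <- fm$y[ord[seq_len(k)]]
    counts <- table(neigh)
    tied <- names(counts)[counts == max(counts)]
    if (length(tied) == 1) {
      return(tied)
    }
    as.character(neigh[match(TRUE, as.character(neigh) %in% tied)])
  })
  factor(labels, levels = classes)
}
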