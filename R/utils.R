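#' @importFrom rlang %||% abort warn
#' @importFrom stats dist predict rnorm runif sd var
NULL

# Extract the numeric feature matrix and the label vector from a data frame.
# Non-numeric columns other than the label (sample ids, file names) are
# carried along as metadata, never as features.
as_feature_matrix <- function(data, label_col = NULL, features = NULL) {
  if (!is.data.frame(data)) {
    data <- as.data.frame(data)
  }
  y <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(data)) {
      abort(paste0("label column `", label_col, "` not found in data"))
    }
    y <- factor(data[[label_col]])
  }
  candidates <- setdiff(names(data), label_col)
  if (is.null(features)) {
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  } else {
    missing <- setdiff(features, names(data))
    if (length(missing)) {
      abort(paste0(
        "feature column mismatch: expected ", length(features),
        " columns, data is missing ", length(missing), " of them (",
        paste(utils::head(missing, 5), collapse = ", "), ")"
      ))
    }
  }
  if (!length(features)) abort("no numeric feature columns found")
  X <- as.matrix(data[features])
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, , drop = TRUE]
    abort(paste0(
      "non-finite feature value at row ", bad[["row"]],
      ", column `", features[bad[["col"]]], "`"
    ))
  }
  list(X = X, y = y, features = features)
}

# Min-max scale columns to [0, 1]; constant columns collapse to 0.
unit_scale <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
  list(X = Xs, lo = lo, span = span)
}

# Moore-Penrose pseudoinverse; singular values below tol * max(sv) are
# treated as zero.
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Evaluate `expr` under a fixed RNG seed, then restore the caller's RNG
# state so model fitting never perturbs the global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Stable sub-seed derivation: hash (master seed, stage name, index) into a
# positive 32-bit integer so every pipeline stage draws from its own
# reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
    collapse = "/"
  )
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h + 1)
}

# Squared Euclidean cross-distance matrix, clamped at zero against
# floating-point cancellation.
cross_dist2 <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

sigmoid <- function(z) 1 / (1 + exp(-z))
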