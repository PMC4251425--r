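#' Kernel extreme learning machine
#'
#' Fits a kernel extreme learning machine (KELM): classes are encoded as
#' signed indicator columns (+1 for the class, -1 otherwise), the kernel
#' Gram matrix \eqn{\Omega} of the training rows is built, and the output
#' coefficients solve the regularised linear system
#' \deqn{(I/C + \Omega)\,\alpha = T}
#' in closed form — no iteration and no randomness. Predictions for a new
#' point are \eqn{f(x) = [K(x, x_1) \ldots K(x, x_n)]\,\alpha}, and the
#' predicted class is the column with the maximal score. With the linear
#' kernel the decision scores coincide with ridge regression on the raw
#' features with penalty `1/C`.
#'
#' The system is solved by Cholesky factorisation for the positive
#' semi-definite kernels (`I/C + Omega` is then positive definite for any
#' finite `C > 0`); the wavelet kernel may yield an indefinite system, which
#' falls back to a general solve and errors only if numerically singular.
#' An explicit matrix inverse is never formed.
#'
#' @param data A data frame holding numeric feature columns and a label
#'   column. Non-numeric columns other than the label are ignored.
#' @param label_col Name of the label column.
#' @param kernel,gamma,degree,coef0 Kernel specification; see
#'   [kernel_matrix()].
#' @param C Positive regularisation penalty; larger values fit the training
#'   targets more tightly.
#' @param log2C,log2gamma Optional log2 parameterisation overriding `C` and
#'   `gamma`, matching the convention of exhaustive grid searches over
#'   integer exponents.
#' @return A `kelm` model object storing the training rows, kernel
#'   specification, penalty and solved coefficients.
#' @seealso [predict.kelm()], [kelm_grid_search()]
#' @export
#' @examples
#' d <- synth_two_class(n_per_class = c(20, 20), n_informative = 2, seed = 1)
#' fit <- kelm(d, "class", kernel = "rbf", C = 1, gamma = 1)
#' head(predict(fit, d))
kelm <- function(data, label_col, kernel = c("rbf", "wavelet", "linear", "polynomial"),
                 C = 1, gamma = 1, degree = 3, coef0 = 1,
                 log2C = NULL, log2gamma = NULL) {
  kernel <- match.arg(kernel)
  if (!is.null(log2C)) C <- 2^log2C
  if (!is.null(log2gamma)) gamma <- 2^log2gamma
  if (!is.numeric(C) || length(C) != 1 || C <= 0) {
    abort("`C` must be a single positive number")
  }
  fm <- as_feature_matrix(data, label_col)
  if (is.null(fm$y)) abort("`label_col` is required")
  classes <- levels(fm$y)
  if (any(table(fm$y) == 0)) abort("every declared class needs at least one sample")
  T_mat <- signed_targets(fm$y)
  omega <- kernel_matrix(fm$X, fm$X,
    kernel = kernel, gamma = gamma,
    degree = degree, coef0 = coef0
  )
  A <- omega
  diag(A) <- diag(A) + 1 / C
  alpha <- solve_sym(A, T_mat, psd = kernel != "wavelet")
  res <- max(abs(A %*% alpha - T_mat)) / max(1, max(abs(T_mat)))

  structure(
    list(
      X_train = fm$X,
      alpha = alpha,
      classes = classes,
      label_col = label_col,
      features = fm$features,
      C = C,
      spec = list(kernel = kernel, gamma = gamma, degree = degree, coef0 = coef0),
      residual = res
    ),
    class = "kelm"
  )
}

#' Predict from a kernel extreme learning machine
#'
#' @param object A fitted [kelm()] model.
#' @param newdata Data frame (or matrix) containing the model's feature
#'   columns.
#' @param type `"class"` for predicted labels, `"score"` for the continuous
#'   decision scores per class (useful for ROC/AUC), or `"both"`.
#' @param ... Unused.
#' @return A factor of labels, a tibble of `.score_*` columns, or a tibble
#'   with `.pred_class` plus the score columns.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  X_new <- newdata_matrix(newdata, object$features)
  scores <- kernel_matrix(X_new, object$X_train,
    kernel = object$spec$kernel, gamma = object$spec$gamma,
    degree = object$spec$degree, coef0 = object$spec$coef0
  ) %*% object$alpha
  finish_prediction(scores, object$classes, type)
}

#' @export
print.kelm <- function(x, ...) {
  cat(
    "KELM:", x$spec$kernel, "kernel, C =", format(x$C),
    if (x$spec$kernel %in% c("rbf", "wavelet")) {
      paste(", gamma =", format(x$spec$gamma))
    } else "",
    "\n  trained on", nrow(x$X_train), "samples x",
    length(x$features), "features; classes:",
    paste(x$classes, collapse = ", "), "\n"
  )
  invisible(x)
}

#' Glance at a KELM model
#'
#' @param x A fitted [kelm()] model.
#' @param ... Unused.
#' @return A one-row tibble with the sample size, feature count, kernel
#'   settings, and the relative residual of the solved linear system.
#' @method glance kelm
#' @export
glance.kelm <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X_train),
    n_features = length(x$features),
    kernel = x$spec$kernel,
    C = x$C,
    gamma = x$spec$gamma,
    residual = x$residual
  )
}

# +1 / -1 indicator matrix, one column per class.
signed_targets <- function(y) {
  classes <- levels(y)
  T_mat <- matrix(-1, length(y), length(classes),
    dimnames = list(NULL, classes)
  )
  T_mat[cbind(seq_along(y), as.integer(y))] <- 1
  T_mat
}

# Symmetric solve: Cholesky when the system is known positive definite,
# otherwise a general dense solve; never an explicit inverse.
solve_sym <- function(A, B, psd = TRUE) {
  if (psd) {
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (!is.null(R)) {
      return(backsolve(R, forwardsolve(t(R), B)))
    }
  }
  tryCatch(
    solve(A, B),
    error = function(e) abort(paste0("kernel system is numerically singular: ", conditionMessage(e)))
  )
}

newdata_matrix <- function(newdata, features) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(features)) {
      abort(paste0(
        "feature dimension mismatch: model expects ", length(features),
        " columns, received ", ncol(newdata)
      ))
    }
    storage.mode(newdata) <- "double"
    return(newdata)
  }
  as_feature_matrix(newdata, features = features)$X
}

finish_prediction <- function(scores, classes, type) {
  labels <- factor(classes[max.col(scores, ties.method = "first")],
    levels = classes
  )
  if (type == "class") {
    return(labels)
  }
  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0(".score_", classes)
  if (type == "score") {
    return(sc)
  }
  dplyr::bind_cols(tibble::tibble(.pred_class = labels), sc)
}
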