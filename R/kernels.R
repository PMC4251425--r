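#' Kernel Gram / cross-kernel matrix
#'
#' Builds the `n x p` matrix of kernel evaluations `K(x_i, y_j)` between the
#' rows of `X` and `Y`. Available kernels:
#'
#' * `rbf`: \eqn{\exp(-\gamma \|x - y\|^2)} — diagonal of `K(X, X)` is
#'   exactly 1.
#' * `linear`: \eqn{x \cdot y}.
#' * `polynomial`: \eqn{(x \cdot y + c_0)^d}.
#' * `wavelet`: the translation-invariant wavelet kernel
#'   \eqn{\prod_d \cos(1.75 (x_d - y_d)/a)\,\exp(-\|x - y\|^2 / (2a^2))}
#'   with dilation \eqn{a = 1/\sqrt{\gamma}}, so the one `gamma` grid
#'   parameter serves every kernel family. This kernel is not positive
#'   semi-definite in general.
#'
#' @param X,Y Numeric matrices (or data frames of numeric columns) with the
#'   same number of columns. `Y` defaults to `X`, giving the Gram matrix.
#' @param kernel One of `"rbf"`, `"wavelet"`, `"linear"`, `"polynomial"`.
#' @param gamma Positive width parameter for the rbf and wavelet kernels.
#' @param degree,coef0 Polynomial kernel degree (positive integer) and
#'   offset.
#' @return An `nrow(X) x nrow(Y)` numeric matrix.
#' @export
#' @examples
#' kernel_matrix(diag(3), kernel = "linear")
kernel_matrix <- function(X, Y = X, kernel = c("rbf", "wavelet", "linear", "polynomial"),
                          gamma = 1, degree = 3, coef0 = 1) {
  kernel <- match.arg(kernel)
  X <- as_points_matrix(X)
  Y <- as_points_matrix(Y)
  if (ncol(X) != ncol(Y)) {
    abort(paste0(
      "feature dimension mismatch: X has ", ncol(X),
      " columns, Y has ", ncol(Y)
    ))
  }
  if (kernel %in% c("rbf", "wavelet")) {
    if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
      abort("`gamma` must be a single positive number")
    }
  }
  switch(kernel,
    rbf = exp(-gamma * cross_dist2(X, Y)),
    linear = tcrossprod(X, Y),
    polynomial = {
      if (degree < 1 || degree != round(degree)) {
        abort("`degree` must be a positive integer")
      }
      (tcrossprod(X, Y) + coef0)^degree
    },
    wavelet = {
      a <- 1 / sqrt(gamma)
      P <- exp(-cross_dist2(X, Y) / (2 * a^2))
      for (d in seq_len(ncol(X))) {
        P <- P * cos(1.75 * outer(X[, d], Y[, d], "-") / a)
      }
      P
    }
  )
}
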