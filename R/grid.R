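#' Exhaustive log2 grid search for KELM parameters
#'
#' Evaluates mean cross-validated accuracy of a KELM on every cell of an
#' integer grid of log2 exponents of the penalty `C` and (for rbf/wavelet
#' kernels) the width `gamma` — the conventional
#' \eqn{[2^{-15}, \ldots, 2^{15}]} sweep with step 1. Ties in accuracy are
#' broken toward smaller `C` and then smaller `gamma`, preferring stronger
#' regularisation. The full accuracy surface is returned for plotting.
#'
#' @inheritParams kfold_cv
#' @param kernel Kernel kind; see [kernel_matrix()].
#' @param log2C,log2gamma Integer exponent vectors defining the grid. For
#'   the linear and polynomial kernels `log2gamma` is ignored (a single
#'   dummy column is used).
#' @param k Folds used for each cell's CV estimate.
#' @param repeats CV repeats per cell (1 by default: the search is already
#'   an average over folds).
#' @return A `kelm_grid` object: `$surface` (tibble of `log2C`,
#'   `log2gamma`, `accuracy`), `$best_log2C`, `$best_log2gamma`,
#'   `$best_accuracy`.
#' @export
#' @examples
#' d <- synth_two_class(n_per_class = c(15, 30), seed = 3)
#' g <- kelm_grid_search(d, "class",
#'   log2C = c(0, 5), log2gamma = c(-5, 0),
#'   k = 3, seed = 9
#' )
#' g$best_log2C
kelm_grid_search <- function(data, label_col, kernel = "rbf",
                             log2C = -15:15, log2gamma = -15:15,
                             k = 10, repeats = 1, seed = 1,
                             weighting = "none", stratified = FALSE,
                             positive = NULL, scfw_args = list()) {
  uses_gamma <- kernel %in% c("rbf", "wavelet")
  if (!uses_gamma) log2gamma <- NA_integer_
  grid <- tidyr::expand_grid(
    log2C = sort(log2C),
    log2gamma = if (uses_gamma) sort(log2gamma) else log2gamma
  )
  acc <- purrr::pmap_dbl(grid, function(log2C, log2gamma) {
    spec <- kelm_spec(
      kernel = kernel, C = 2^log2C,
      gamma = if (uses_gamma) 2^log2gamma else 1
    )
    rep <- kfold_cv(data, label_col, spec,
      k = k, repeats = repeats, seed = seed,
      weighting = weighting, stratified = stratified,
      positive = positive, scfw_args = scfw_args
    )
    rep$summary$mean[rep$summary$metric == "accuracy"]
  })
  surface <- dplyr::mutate(grid, accuracy = acc)
  # rows are ordered by (log2C, log2gamma); which.max takes the first
  # maximum, i.e. smaller C then smaller gamma on ties
  best <- which.max(surface$accuracy)

  structure(
    list(
      surface = surface,
      best_log2C = surface$log2C[best],
      best_log2gamma = surface$log2gamma[best],
      best_accuracy = surface$accuracy[best],
      kernel = kernel, k = k, repeats = repeats, seed = seed,
      weighting = weighting
    ),
    class = "kelm_grid"
  )
}

#' @export
print.kelm_grid <- function(x, ...) {
  cat(
    "KELM grid search (", x$kernel, "kernel,", nrow(x$surface), "cells ):",
    "best accuracy", sprintf("%.2f%%", x$best_accuracy),
    "at log2C =", x$best_log2C,
    if (!is.na(x$best_log2gamma)) paste(", log2gamma =", x$best_log2gamma) else "",
    "\n"
  )
  invisible(x)
}

#' Tidy a grid-search result
#'
#' @param x A `kelm_grid`.
#' @param ... Unused.
#' @return The accuracy surface tibble.
#' @method tidy kelm_grid
#' @export
tidy.kelm_grid <- function(x, ...) {
  x$surface
}

#' Plot a grid-search accuracy surface
#'
#' @param object A `kelm_grid`.
#' @param ... Unused.
#' @return A ggplot raster of mean CV accuracy over the (log2C, log2gamma)
#'   grid, or a line over log2C for kernels without a width parameter.
#' @method autoplot kelm_grid
#' @export
autoplot.kelm_grid <- function(object, ...) {
  s <- object$surface
  if (all(is.na(s$log2gamma))) {
    return(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$log2C, y = .data$accuracy)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::labs(y = "mean CV accuracy (%)") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(s, ggplot2::aes(
    x = .data$log2C, y = .data$log2gamma, fill = .data$accuracy
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "accuracy (%)") +
    ggplot2::labs(
      title = paste("KELM", object$kernel, "accuracy surface"),
      x = "log2 C", y = "log2 gamma"
    ) +
    ggplot2::theme_minimal()
}
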