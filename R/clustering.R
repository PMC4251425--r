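#' Density measure for subtractive clustering
#'
#' Computes, for every data point, the Gaussian-kernel density
#' \deqn{D_i = \sum_j \exp\left(-\frac{\|x_i - x_j\|^2}{(r_a/2)^2}\right),}
#' where `r_a` is the neighbourhood radius. Points with many close
#' neighbours receive a high density; points beyond the radius contribute
#' negligibly. The self-term contributes exactly 1, so `1 <= D_i <= n`.
#'
#' @param points A numeric matrix, data frame of numeric columns, or vector
#'   (treated as one-dimensional points).
#' @param r_a Positive neighbourhood radius.
#' @return A numeric vector of densities, one per point.
#' @seealso [find_centers()]
#' @export
#' @examples
#' density_measure(c(0, 0.25, 1), r_a = 0.5)
density_measure <- function(points, r_a = 0.5) {
  X <- as_points_matrix(points)
  if (!is.numeric(r_a) || length(r_a) != 1 || !is.finite(r_a) || r_a <= 0) {
    abort("`r_a` must be a single positive number")
  }
  rowSums(exp(-cross_dist2(X, X) / (r_a / 2)^2))
}

#' Revise densities after selecting a cluster center
#'
#' Subtracts from every point's density the selected center's density
#' attenuated by distance,
#' \eqn{D_i \leftarrow D_i - D_c \exp(-\|x_i - x_c\|^2 / (r_b/2)^2)},
#' suppressing the neighbourhood of the chosen center so the next center
#' emerges elsewhere. The revised density at the center itself is exactly 0;
#' revised densities may go negative and are deliberately not clipped —
#' negative points simply never win the next argmax.
#'
#' @param densities Numeric vector of current densities.
#' @param points The points the densities belong to (same row order).
#' @param center_index Index of the just-selected center (the argmax of
#'   `densities`).
#' @param r_b Positive suppression radius, larger than the neighbourhood
#'   radius so centers are not selected in close proximity.
#' @return The revised density vector.
#' @export
revise_density <- function(densities, points, center_index, r_b = 0.8) {
  X <- as_points_matrix(points)
  n <- nrow(X)
  if (length(densities) != n) {
    abort("`densities` must have one entry per point")
  }
  if (!is.numeric(center_index) || length(center_index) != 1 ||
    center_index < 1 || center_index > n) {
    abort(paste0("`center_index` out of range [1, ", n, "]"))
  }
  if (!is.numeric(r_b) || length(r_b) != 1 || !is.finite(r_b) || r_b <= 0) {
    abort("`r_b` must be a single positive number")
  }
  d_c <- densities[center_index]
  d2 <- cross_dist2(X, X[center_index, , drop = FALSE])[, 1]
  out <- densities - d_c * exp(-d2 / (r_b / 2)^2)
  # guard the center itself against round-off: the self-term subtracts all
  out[center_index] <- 0
  out
}

#' Subtractive clustering
#'
#' Greedy density-based clustering in which every data point is a candidate
#' center. The highest-density point is selected, densities in its
#' neighbourhood are suppressed ([revise_density()]), and selection repeats
#' until the best remaining candidate's density falls below
#' `accept_ratio` times the first center's density (or `max_centers` is
#' reached). Every returned center is one of the input rows, so centers are
#' always realisable data points.
#'
#' Because the density radius is dimensionless while real feature tables mix
#' units spanning orders of magnitude, each dimension is min-max scaled to
#' \[0, 1\] before the density computation by default; the returned centers
#' are reported in the original coordinates. Set `scale = FALSE` to cluster
#' in raw coordinates.
#'
#' @inheritParams density_measure
#' @param r_b Suppression radius; defaults to `eta * r_a`.
#' @param eta Ratio `r_b / r_a`, a constant greater than 1 that keeps
#'   centers apart. Used only when `r_b` is not supplied; when both are
#'   given they must agree.
#' @param accept_ratio Stopping threshold in (0, 1]: selection stops when
#'   the candidate density drops below `accept_ratio` times the first
#'   center's density.
#' @param max_centers Optional hard cap on the number of centers.
#' @param scale Min-max scale each dimension to \[0, 1\] before clustering.
#' @return An object of class `subclust` with elements `centers` (matrix in
#'   input coordinates, one row per center in selection order), `indices`
#'   (rows of the input chosen), `densities` (density of each center at
#'   selection time, non-increasing), and `params`.
#' @export
#' @examples
#' pts <- c(rep(0, 10), rep(1, 10))
#' find_centers(pts, r_a = 0.5, accept_ratio = 0.15)
find_centers <- function(points, r_a = 0.5, r_b = NULL, eta = 1.6,
                         accept_ratio = 0.15, max_centers = Inf,
                         scale = TRUE) {
  X <- as_points_matrix(points)
  if (is.null(r_b)) {
    if (!is.numeric(eta) || length(eta) != 1 || eta <= 1) {
      abort("`eta` must be a single number greater than 1")
    }
    r_b <- eta * r_a
  } else if (!missing(eta) && abs(r_b - eta * r_a) > 1e-12) {
    abort("`r_b` must equal `eta * r_a` when both are supplied")
  }
  if (r_b <= r_a) abort("`r_b` must exceed `r_a`")
  if (!is.numeric(accept_ratio) || length(accept_ratio) != 1 ||
    accept_ratio <= 0 || accept_ratio > 1) {
    abort("`accept_ratio` must lie in (0, 1]")
  }
  if (max_centers < 1) abort("`max_centers` must be at least 1")

  Xw <- if (scale) unit_scale(X)$X else X
  dens <- density_measure(Xw, r_a)

  idx <- integer(0)
  sel_dens <- numeric(0)
  d_first <- NA_real_
  repeat {
    cand <- which.max(dens) # ties resolve to the lowest index
    d_cand <- dens[cand]
    if (length(idx) == 0) {
      d_first <- d_cand
    } else if (d_cand <= 0 || d_cand < accept_ratio * d_first) {
      break
    }
    idx <- c(idx, cand)
    sel_dens <- c(sel_dens, d_cand)
    if (length(idx) >= max_centers) break
    dens <- revise_density(dens, Xw, cand, r_b)
  }

  structure(
    list(
      centers = X[idx, , drop = FALSE],
      indices = idx,
      densities = sel_dens,
      params = list(
        r_a = r_a, r_b = r_b, accept_ratio = accept_ratio,
        max_centers = max_centers, scale = scale
      ),
      n = nrow(X)
    ),
    class = "subclust"
  )
}

#' @export
print.subclust <- function(x, ...) {
  cat(
    "Subtractive clustering:", length(x$indices), "center(s) from",
    x$n, "points (r_a =", x$params$r_a, ", r_b =", x$params$r_b, ")\n"
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a subtractive-clustering result
#'
#' @param x A `subclust` object from [find_centers()].
#' @param ... Unused.
#' @return A tibble with one row per center: selection order, input row
#'   index, selection-time density, and the center coordinates.
#' @method tidy subclust
#' @export
tidy.subclust <- function(x, ...) {
  coords <- tibble::as_tibble(x$centers, .name_repair = "minimal")
  if (is.null(colnames(x$centers))) {
    names(coords) <- paste0("x", seq_len(ncol(x$centers)))
  }
  dplyr::bind_cols(
    tibble::tibble(
      center = seq_along(x$indices),
      row = x$indices,
      density = x$densities
    ),
    coords
  )
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as_feature_matrix(points)$X
  }
  if (is.vector(points) && is.numeric(points)) {
    points <- matrix(points, ncol = 1)
  }
  if (!is.matrix(points) || !is.numeric(points)) {
    abort("`points` must be a numeric matrix, data frame or vector")
  }
  if (nrow(points) < 1) abort("`points` must contain at least one row")
  if (anyNA(points) || !all(is.finite(points))) {
    abort("`points` must be finite and free of missing values")
  }
  storage.mode(points) <- "double"
  points
}
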