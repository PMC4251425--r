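#' Measure the benefit of SCFW weighting on the reference benchmark
#'
#' Runs the package's frozen non-separable benchmark ([synth_benchmark()])
#' once per seed and evaluates two otherwise-identical arms: rbf-kernel
#' KELM on the raw features, and the same classifier on SCFW-weighted
#' features (whole-table weighting, the historical two-stage protocol).
#' Each arm first selects its penalty and width on a coarse log2 grid by
#' k-fold CV — mirroring how such classifiers are tuned in practice — and
#' is then scored by 10-fold CV at the selected cell.
#'
#' @param seeds Integer vector of benchmark seeds (one dataset per seed).
#' @param log2C,log2gamma Grid of exponents searched per arm.
#' @param search_k Folds used during the grid search.
#' @param k Folds of the final evaluation.
#' @return A tibble with one row per seed and arm: `seed`, `weighting`,
#'   `accuracy`, `auc`, `f_measure`, `kappa` (means over the final CV
#'   folds), plus the selected `log2C` and `log2gamma`.
#' @export
#' @examples
#' \donttest{
#' bench <- scfw_benefit_benchmark(seeds = 1:3)
#' dplyr::group_by(bench, weighting) |> dplyr::summarise(acc = mean(accuracy))
#' }
scfw_benefit_benchmark <- function(seeds = 1:20,
                                   log2C = seq(-5, 15, 5),
                                   log2gamma = seq(-15, 5, 5),
                                   search_k = 5, k = 10) {
  arms <- tidyr::expand_grid(seed = seeds, weighting = c("whole", "none"))
  purrr::pmap_dfr(arms, function(seed, weighting) {
    d <- synth_benchmark(seed)
    g <- kelm_grid_search(d, "class",
      kernel = "rbf",
      log2C = log2C, log2gamma = log2gamma,
      k = search_k, seed = seed, weighting = weighting
    )
    r <- kfold_cv(d, "class",
      kelm_spec("rbf", log2C = g$best_log2C, log2gamma = g$best_log2gamma),
      k = k, repeats = 1, seed = seed, weighting = weighting
    )
    s <- r$summary
    pick <- function(m) s$mean[s$metric == m]
    tibble::tibble(
      seed = seed,
      weighting = weighting,
      accuracy = pick("accuracy"),
      auc = pick("auc"),
      f_measure = pick("f_measure"),
      kappa = pick("kappa"),
      log2C = g$best_log2C,
      log2gamma = g$best_log2gamma
    )
  })
}
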