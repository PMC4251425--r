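#' Classifier specifications for the cross-validation harness
#'
#' Lightweight descriptions of a classifier to be fitted inside each CV
#' fold. `kelm_spec()` accepts either natural (`C`, `gamma`) or log2
#' parameters; `elm_spec()` fixes the hidden-layer size (the random layer
#' is re-drawn per fold from a derived seed); `knn_spec()` fixes the
#' neighbourhood size.
#'
#' @param kernel,C,gamma,degree,coef0,log2C,log2gamma See [kelm()].
#' @return A `clf_spec` object.
#' @export
kelm_spec <- function(kernel = "rbf", C = 1, gamma = 1, degree = 3, coef0 = 1,
                      log2C = NULL, log2gamma = NULL) {
  if (!is.null(log2C)) C <- 2^log2C
  if (!is.null(log2gamma)) gamma <- 2^log2gamma
  structure(
    list(
      method = "kelm", kernel = kernel, C = C, gamma = gamma,
      degree = degree, coef0 = coef0
    ),
    class = "clf_spec"
  )
}

#' @rdname kelm_spec
#' @param hidden Hidden-neuron count for the ELM.
#' @export
elm_spec <- function(hidden = 20) {
  structure(list(method = "elm", hidden = hidden), class = "clf_spec")
}

#' @rdname kelm_spec
#' @param k Neighbourhood size for k-NN.
#' @export
knn_spec <- function(k = 1) {
  structure(list(method = "knn", k = k), class = "clf_spec")
}

clf_label <- function(spec) {
  switch(spec$method,
    kelm = sprintf(
      "kelm(%s, C=%g%s)", spec$kernel, spec$C,
      if (spec$kernel %in% c("rbf", "wavelet")) sprintf(", gamma=%g", spec$gamma) else ""
    ),
    elm = sprintf("elm(hidden=%d)", spec$hidden),
    knn = sprintf("knn(k=%d)", spec$k)
  )
}

# Fit on a training table and score a held-out table; returns predicted
# labels plus the positive-class continuous score (NULL for knn).
clf_fit_predict <- function(spec, train, test, label_col, positive, fold_seed) {
  if (spec$method == "kelm") {
    fit <- kelm(train, label_col,
      kernel = spec$kernel, C = spec$C,
      gamma = spec$gamma, degree = spec$degree, coef0 = spec$coef0
    )
    pred <- predict(fit, test, type = "both")
  } else if (spec$method == "elm") {
    fit <- elm(train, label_col, hidden = spec$hidden, seed = fold_seed)
    pred <- predict(fit, test, type = "both")
  } else if (spec$method == "knn") {
    cls <- knn_classify(train, label_col, test, k = spec$k)
    return(list(class = cls, score = NULL))
  } else {
    abort(paste0("unknown classifier method: ", spec$method))
  }
  score_col <- paste0(".score_", positive)
  list(
    class = pred$.pred_class,
    score = if (score_col %in% names(pred)) pred[[score_col]] else NULL
  )
}

# Seeded partition of n rows into k near-equal folds (sizes differ by at
# most one); optionally stratified by class.
make_folds <- function(n, k, seed, strata = NULL, stratified = FALSE) {
  if (k < 2) abort("`k` must be at least 2")
  if (k > n) abort(paste0("`k` (", k, ") exceeds the number of samples (", n, ")"))
  with_local_seed(seed, {
    if (stratified && !is.null(strata)) {
      fold <- integer(n)
      for (cl in unique(strata)) {
        rows <- which(strata == cl)
        fold[rows[sample.int(length(rows))]] <-
          rep_len(sample.int(k), length(rows))
      }
      fold
    } else {
      rep_len(sample.int(k), n)[sample.int(n)]
    }
  })
}

#' Repeated k-fold cross-validation
#'
#' Seeded, repeated k-fold evaluation of a classifier, optionally preceded
#' by SCFW feature weighting. Each repeat draws a fresh random partition
#' into `k` near-equal folds (sizes differ by at most one); each fold is
#' held out once, the classifier is fitted on the remaining folds, and the
#' held-out confusion matrix yields the diagnostic panel of
#' [classification_metrics()] plus rank-based AUC from the continuous
#' decision scores. Identical `seed` gives an identical report.
#'
#' Weighting modes:
#' * `"none"` — classify the raw features;
#' * `"whole"` — fit the SCFW transform once on the full table before
#'   splitting (the historical protocol of two-stage diagnosis pipelines;
#'   optimistic, since held-out rows inform the weights);
#' * `"fold"` — refit the transform inside every training split and apply
#'   it to the held-out fold, the leakage-free protocol recommended for
#'   honest generalisation estimates.
#'
#' @param data Feature table with a label column.
#' @param label_col Name of the label column.
#' @param classifier A `clf_spec` from [kelm_spec()], [elm_spec()] or
#'   [knn_spec()].
#' @param k Number of folds.
#' @param repeats Number of repeated partitions.
#' @param seed Master seed; per-repeat and per-fold sub-seeds are derived
#'   deterministically from it.
#' @param weighting `"none"`, `"whole"` or `"fold"`.
#' @param stratified Stratify the partition by class (off by default; with
#'   a small minority class unstratified folds can lose a class, which is
#'   reported as NaN metrics rather than silently fixed).
#' @param positive Positive-class label; defaults to the last factor
#'   level.
#' @param scfw_args Extra arguments passed to [scfw_fit()].
#' @return A `cv_report` object: per-fold tibble (`$folds`), aggregate
#'   mean/SD/max/min per metric (`$summary`), and the run settings. See
#'   [tidy.cv_report()], [glance.cv_report()], [autoplot.cv_report()].
#' @export
#' @examples
#' d <- synth_two_class(n_per_class = c(20, 40), seed = 2)
#' rep <- kfold_cv(d, "class", kelm_spec("rbf", log2C = 5, log2gamma = -5),
#'   k = 5, repeats = 2, seed = 42
#' )
#' glance(rep)
kfold_cv <- function(data, label_col, classifier = kelm_spec(),
                     k = 10, repeats = 10, seed = 1,
                     weighting = c("none", "whole", "fold"),
                     stratified = FALSE, positive = NULL,
                     scfw_args = list()) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(classifier, "clf_spec"))
  t0 <- proc.time()[["elapsed"]]
  y <- factor(data[[label_col]] %||% abort(paste0("label column `", label_col, "` not found")))
  positive <- if (is.null(positive)) levels(y)[nlevels(y)] else as.character(positive)
  n <- nrow(data)

  data_used <- data
  transform <- NULL
  if (weighting == "whole") {
    transform <- do.call(scfw_fit, c(list(data, label_col), scfw_args))
    data_used <- predict(transform, data)
  }

  rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- make_folds(n, k, derive_seed(seed, "folds", r),
      strata = y, stratified = stratified
    )
    for (f in seq_len(k)) {
      test_idx <- which(fold_id == f)
      train <- data_used[-test_idx, , drop = FALSE]
      test <- data_used[test_idx, , drop = FALSE]
      if (weighting == "fold") {
        tr <- do.call(scfw_fit, c(list(train, label_col), scfw_args))
        train <- predict(tr, train)
        test <- predict(tr, test)
      }
      pred <- clf_fit_predict(
        classifier, train, test, label_col, positive,
        fold_seed = derive_seed(seed, "clf", r, f)
      )
      cm <- confusion_matrix(test[[label_col]], pred$class, positive = positive)
      met <- suppressWarnings(classification_metrics(cm))
      auc <- if (is.null(pred$score)) {
        NA_real_
      } else {
        suppressWarnings(auc_from_scores(pred$score, test[[label_col]], positive))
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          repeat_id = r, fold = f, n_test = length(test_idx),
          tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn
        ),
        met,
        tibble::tibble(auc = auc)
      )
    }
  }
  folds <- dplyr::bind_rows(rows)

  metric_cols <- c(
    "accuracy", "sensitivity", "specificity", "auc",
    "precision", "recall", "f_measure", "kappa"
  )
  summary <- folds |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, metric_cols))

  structure(
    list(
      folds = folds,
      summary = summary,
      transform = transform,
      classifier = classifier,
      weighting = weighting,
      k = k, repeats = repeats, seed = seed,
      positive = positive,
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    "Repeated k-fold CV:", clf_label(x$classifier),
    "| weighting:", x$weighting,
    "| k =", x$k, ", repeats =", x$repeats, ", seed =", x$seed, "\n"
  )
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The aggregate tibble: one row per metric with mean, SD, max and
#'   min over all folds and repeats (accuracy, sensitivity, specificity
#'   and AUC in percent; precision, recall, f-measure and kappa on
#'   \[0, 1\]).
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  x$summary
}

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble with the mean of each metric plus the run
#'   settings.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  wide <- x$summary |>
    dplyr::select("metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  acc_sd <- x$summary$sd[x$summary$metric == "accuracy"]
  dplyr::bind_cols(
    wide,
    tibble::tibble(
      accuracy_sd = acc_sd,
      k = x$k, repeats = x$repeats, seed = x$seed,
      weighting = x$weighting,
      classifier = clf_label(x$classifier),
      elapsed = x$elapsed
    )
  )
}

#' Plot per-fold accuracy of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param metric Which per-fold metric to plot.
#' @param ... Unused.
#' @return A ggplot: per-repeat boxplots of the chosen fold-level metric.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, metric = "accuracy", ...) {
  stopifnot(metric %in% names(object$folds))
  ggplot2::ggplot(object$folds, ggplot2::aes(
    x = factor(.data$repeat_id), y = .data[[metric]]
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(
      x = "repeat", y = metric,
      title = paste0(
        "Per-fold ", metric, " — ", clf_label(object$classifier),
        " (weighting: ", object$weighting, ")"
      )
    ) +
    ggplot2::theme_minimal()
}
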