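#' Binary confusion matrix
#'
#' Tallies a binary confusion matrix with rows read as actual classes and
#' columns as predicted classes: TP and FN count actual positives predicted
#' positive/negative, FP and TN count actual negatives.
#'
#' @param truth Vector of true labels (two classes).
#' @param estimate Vector of predicted labels, same length.
#' @param positive The label treated as the positive (disease) class.
#'   Defaults to the last factor level, so 0/1 status coding makes 1
#'   positive.
#' @return A `confusion_matrix` object with fields `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
confusion_matrix <- function(truth, estimate, positive = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length")
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  classes <- sort(unique(c(truth, estimate)))
  if (length(classes) > 2) abort("confusion_matrix() is binary only")
  positive <- if (is.null(positive)) classes[length(classes)] else as.character(positive)
  if (!positive %in% classes) {
    abort(paste0("positive class `", positive, "` not present in the labels"))
  }
  is_pos <- truth == positive
  pred_pos <- estimate == positive
  new_confusion(
    tp = sum(is_pos & pred_pos), fn = sum(is_pos & !pred_pos),
    fp = sum(!is_pos & pred_pos), tn = sum(!is_pos & !pred_pos),
    positive = positive
  )
}

#' Build a confusion matrix from its four counts
#'
#' Useful for re-deriving metrics from published confusion tables.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param positive Label of the positive class (for printing only).
#' @return A `confusion_matrix` object.
#' @export
new_confusion <- function(tp, fn, fp, tn, positive = "1") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, dimnames = list(
    actual = c(paste0(x$positive, " (pos)"), "neg"),
    predicted = c("pos", "neg")
  ))
  print(m)
  invisible(x)
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Computes the standard binary diagnostic panel:
#' \deqn{ACC = \frac{TP+TN}{TP+FP+FN+TN} \times 100\%,}
#' sensitivity \eqn{TP/(TP+FN)} and specificity \eqn{TN/(FP+TN)} (both as
#' percentages), precision, recall, their harmonic mean (f-measure), and
#' Cohen's kappa
#' \eqn{\kappa = (P(A) - P(E)) / (1 - P(E))} with observed agreement
#' \eqn{P(A) = (TP+TN)/n} and chance agreement \eqn{P(E)} from the row and
#' column marginals. Any metric with a zero denominator is returned as
#' `NaN` with a warning rather than raising an error, so sweeps over many
#' folds never abort on a degenerate fold.
#'
#' @param cm A `confusion_matrix` (from [confusion_matrix()] or
#'   [new_confusion()]).
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity` (percent), `precision`, `recall`, `f_measure`, `kappa`,
#'   `p_a`, `p_e`.
#' @export
#' @examples
#' classification_metrics(new_confusion(tp = 146, fn = 1, fp = 0, tn = 48))
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp
  fn <- cm$fn
  fp <- cm$fp
  tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n == 0) abort("empty confusion matrix")

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); returning NaN"))
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity/recall")
  spec <- safe_div(tn, fp + tn, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    warn("f-measure undefined; returning NaN")
    NaN
  } else {
    2 * prec * sens / (prec + sens)
  }
  p_a <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (p_e == 1) {
    warn("kappa undefined (chance agreement is 1); returning NaN")
    NaN
  } else {
    (p_a - p_e) / (1 - p_e)
  }

  tibble::tibble(
    accuracy = 100 * p_a,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    precision = prec,
    recall = sens,
    f_measure = f,
    kappa = kappa,
    p_a = p_a,
    p_e = p_e
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A four-row tibble of cell counts.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fn", "fp", "tn"),
    count = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Area under the ROC curve from continuous scores
#'
#' Rank-based (Mann-Whitney) AUC of a continuous positive-class score:
#' the probability that a random positive scores above a random negative,
#' with ties counted one half. Equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric decision scores, larger meaning more positive.
#' @param truth True labels.
#' @param positive Positive-class label; defaults as in
#'   [confusion_matrix()].
#' @return AUC as a percentage; `NaN` (with a warning) if either class is
#'   absent.
#' @export
auc_from_scores <- function(scores, truth, positive = NULL) {
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length")
  }
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  positive <- if (is.null(positive)) classes[length(classes)] else as.character(positive)
  pos <- truth == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUC undefined: only one class present; returning NaN")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
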