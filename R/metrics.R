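#' Build a confusion-count record
#'
#' The four cells of a binary confusion matrix from which every downstream
#' evaluation metric derives.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return A one-row tibble of class `confusion_counts` with columns
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(tp = 289, tn = 386, fp = 11, fn = 25)
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  if (sum(counts) == 0) {
    abort("Confusion counts are all zero; no observations to evaluate.")
  }
  out <- tibble::tibble(tp = as.integer(tp), tn = as.integer(tn),
                        fp = as.integer(fp), fn = as.integer(fn))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Confusion counts from predicted class probabilities
#'
#' Thresholds predicted probabilities at `threshold` (class 1 iff
#' probability > threshold) and tabulates against the true labels.
#'
#' @param truth Binary vector of true labels (0/1, logical, or a factor whose
#'   second level is the positive class).
#' @param prob Numeric vector of predicted probabilities of the positive class.
#' @param threshold Classification threshold on the probability; default 0.5.
#' @return A `confusion_counts` tibble.
#' @export
confusion_from_probs <- function(truth, prob, threshold = 0.5) {
  truth <- as_binary_labels(truth)
  if (length(truth) != length(prob)) {
    abort("`truth` and `prob` must have equal length.")
  }
  pred <- as.integer(prob > threshold)
  confusion_counts(
    tp = sum(pred == 1 & truth == 1),
    tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1)
  )
}

as_binary_labels <- function(truth) {
  if (is.factor(truth)) {
    if (nlevels(truth) != 2) abort("Factor labels must have exactly two levels.")
    return(as.integer(truth == levels(truth)[2]))
  }
  if (is.logical(truth)) return(as.integer(truth))
  truth <- as.numeric(truth)
  if (!all(truth %in% c(0, 1))) abort("Labels must be binary (0/1).")
  as.integer(truth)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall (sensitivity), specificity, F1 and the
#' Matthews correlation coefficient from the four confusion-matrix cells.
#' A metric whose denominator is zero is reported as `NA` (explicitly
#' undefined), never silently coerced to 0.
#'
#' @param counts A `confusion_counts` record, or anything coercible via
#'   `confusion_counts()` when `tp`/`tn`/`fp`/`fn` are passed instead.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`, `mcc`.
#' @examples
#' classification_metrics(confusion_counts(289, 386, 11, 25))
#' @export
classification_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    check_columns(counts, c("tp", "tn", "fp", "fn"), "`counts`")
    counts <- confusion_counts(counts$tp[1], counts$tn[1], counts$fp[1], counts$fn[1])
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  # F1 as tp / (tp + (fp+fn)/2): the harmonic mean of precision and recall,
  # defined directly from counts so it survives precision/recall of 0.
  f1 <- safe_div(tp, tp + (fp + fn) / 2)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tn * tp - fp * fn) / mcc_den
  tibble::tibble(
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, specificity = specificity,
    f1 = f1, mcc = mcc
  )
}

#' ROC curve and AUC by rank statistic
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen positive
#' outscores a randomly chosen negative, computed from midranks so ties
#' contribute 1/2. The curve itself comes from a sweep over all observed
#' score thresholds.
#'
#' @param truth Binary true labels (see [confusion_from_probs()]).
#' @param score Numeric scores; larger means more positive.
#' @return An object of class `roc_result`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(truth, score) {
  truth <- as_binary_labels(truth)
  if (length(truth) != length(score)) abort("`truth` and `score` lengths differ.")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to compute a ROC curve.")
  }
  # Mann-Whitney AUC with midrank tie handling.
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- score >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(pred & truth == 0) / n_neg,
      tpr = sum(pred & truth == 1) / n_pos
    )
  })
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(truth, score) {
  roc_curve(truth, score)$auc
}

# Trapezoidal area under the threshold-sweep curve; equals the rank AUC and
# is used as the internal consistency check.
trapezoid_auc <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- points$fpr[o]; y <- points$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @exportS3Method
tidy.roc_result <- function(x, ...) x$points

#' @exportS3Method
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$points))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @exportS3Method
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)
    ) +
    ggplot2::coord_equal()
}
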