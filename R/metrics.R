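#' Confusion matrix and derived classification metrics
#'
#' Cross-tabulates predictions against true labels into TP/FP/TN/FN and the
#' three standard ratios: accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(FP+TN)`.
#'
#' @param predictions,labels Equal-length vectors over the same two classes.
#' @param positive The positive (patient) class label.
#' @return A `meg_confusion` object (also a list): `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `positive`.
#' @export
confusion_metrics <- function(predictions, labels, positive) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  classes <- unique(labels)
  if (!positive %in% classes) {
    stop("positive class '", positive, "' absent from labels", call. = FALSE)
  }
  if (!all(predictions %in% classes)) {
    stop("predictions contain labels outside the label domain", call. = FALSE)
  }
  pos_t <- labels == positive
  pos_p <- predictions == positive
  new_confusion(tp = sum(pos_p & pos_t), fp = sum(pos_p & !pos_t),
                tn = sum(!pos_p & !pos_t), fn = sum(!pos_p & pos_t),
                positive = positive)
}

#' Reconstruct an integer confusion matrix from published rates
#'
#' Given the two class sizes and the reported sensitivity and specificity,
#' recovers the integer TP/FN/TN/FP counts (`TP = round(sens * n_pos)` etc.)
#' and the metrics they imply. Useful for checking that published accuracy,
#' sensitivity and specificity are mutually consistent.
#'
#' @param n_pos,n_neg Positive- and negative-class sizes.
#' @param sensitivity,specificity Reported rates in [0, 1].
#' @param positive Positive class label to attach.
#' @return A `meg_confusion` object.
#' @examples
#' # 16 patients vs 102 controls at sens .750 / spec .971
#' confusion_from_rates(16, 102, 0.750, 0.971)
#' @export
confusion_from_rates <- function(n_pos, n_neg, sensitivity, specificity,
                                 positive = "patient") {
  stopifnot(n_pos >= 1, n_neg >= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  new_confusion(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn,
                positive = positive)
}

new_confusion <- function(tp, fp, tn, fn, positive) {
  total <- tp + fp + tn + fn
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / total,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
         positive = positive),
    class = "meg_confusion"
  )
}

#' @export
print.meg_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive = %s)\n", x$positive))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
tidy.meg_confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' ROC curve and trapezoidal AUC from posterior probabilities
#'
#' Sweeps the classification threshold over the unique posterior values
#' (tied scores enter the curve at a single threshold step, plus sentinels
#' so the curve runs from (0,0) to (1,1)) and integrates the area under the
#' curve with the trapezoidal rule.
#'
#' @param posteriors Scores in [0, 1] (probability of the positive class).
#' @param labels True class per sample; both classes must be present.
#' @param positive Positive class label.
#' @return A `meg_roc` object: `$points` tibble (`threshold`, `fpr`, `tpr`)
#'   and `$auc`.
#' @export
roc_curve <- function(posteriors, labels, positive) {
  labels <- as.character(labels)
  if (!positive %in% labels || all(labels == positive)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (any(posteriors < 0 | posteriors > 1)) {
    stop("posteriors must lie in [0, 1]", call. = FALSE)
  }
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  thr <- c(Inf, sort(unique(posteriors), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    called <- posteriors >= t
    tibble::tibble(threshold = t,
                   fpr = sum(called & !is_pos) / n_neg,
                   tpr = sum(called & is_pos) / n_pos)
  })
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive = positive),
            class = "meg_roc")
}

#' @export
print.meg_roc <- function(x, ...) {
  cat(sprintf("ROC (positive = %s): %d thresholds, AUC = %.3f\n",
              x$positive, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.meg_roc <- function(x, ...) x$points

#' @export
glance.meg_roc <- function(x, ...) {
  tibble::tibble(positive = x$positive, auc = x$auc,
                 n_thresholds = nrow(x$points))
}
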