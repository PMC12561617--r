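# Multi-class evaluation metrics. For each class a one-vs-rest reduction
# of the confusion matrix gives TP/FP/TN/FN; precision, recall, F1 and
# specificity are computed per class and macro-averaged. Accuracy is the
# trace of the confusion matrix over the total count.

#' Confusion matrix
#'
#' @param truth Integer true class labels in `1..n_classes`.
#' @param pred Integer predicted labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param levels Optional class names for dimnames.
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class; the entries sum to `length(truth)`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred),
                             levels = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1,
            all(truth >= 1), all(pred >= 1),
            all(truth <= n_classes), all(pred <= n_classes))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (!is.null(levels)) dimnames(cm) <- list(truth = levels, pred = levels)
  cm
}

#' Multi-class metrics report
#'
#' Computes accuracy (correct predictions over total), and per-class
#' one-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1
#' `2PR/(P+R)` and specificity `TN/(TN+FP)`, together with their macro
#' averages (unweighted mean over classes). A class absent from both the
#' truth and the predictions contributes zeros and is flagged in
#' `$absent_classes`. Zero denominators yield zero (flagged cases aside,
#' this happens when a class is never predicted).
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return A `metrics_report`: list with `accuracy`, macro `precision`,
#'   `recall`, `f1`, `specificity`, a `per_class` data frame, and
#'   `absent_classes`.
#' @export
metrics_report <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  absent <- which(rowSums(cm) + colSums(cm) == 0)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  specificity <- safe_div(tn, tn + fp)
  if (length(absent)) {
    precision[absent] <- recall[absent] <- 0
    f1[absent] <- specificity[absent] <- 0
  }
  per_class <- data.frame(
    class = if (!is.null(dimnames(cm)[[1]])) dimnames(cm)[[1]]
            else as.character(seq_len(K)),
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    specificity = specificity, row.names = NULL)
  structure(list(
    accuracy = sum(tp) / total,
    precision = mean(precision), recall = mean(recall),
    f1 = mean(f1), specificity = mean(specificity),
    per_class = per_class,
    absent_classes = per_class$class[absent]),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f recall %.4f f1 %.4f specificity %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$specificity))
  if (length(x$absent_classes))
    cat("absent classes (metrics set to 0):",
        paste(x$absent_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Accuracy/latency tradeoff factor
#'
#' `theta = (acc_baseline - acc_method) - (t_baseline - t_method)`:
#' accuracies in percent and per-image inference times in milliseconds
#' are subtracted as printed, with no unit normalization. Lower is better;
#' zero for identical pairs; negative when a method is faster at equal
#' accuracy.
#'
#' @param acc_baseline,acc_method Test accuracies in percent.
#' @param t_baseline,t_method Mean per-image inference times in
#'   milliseconds (positive).
#' @return A `tradeoff_result` with `theta` and the four inputs.
#' @export
tradeoff_factor <- function(acc_baseline, acc_method, t_baseline, t_method) {
  stopifnot(t_baseline > 0, t_method > 0)
  structure(list(theta = (acc_baseline - acc_method) - (t_baseline - t_method),
                 acc_baseline = acc_baseline, acc_method = acc_method,
                 t_baseline = t_baseline, t_method = t_method),
            class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf("theta = %.4f  (acc %0.3f%% -> %0.3f%%, t %.3f ms -> %.3f ms)\n",
              x$theta, x$acc_baseline, x$acc_method, x$t_baseline, x$t_method))
  invisible(x)
}
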