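# Evaluation over the extended label set (known classes + the unknown
# marker): confusion matrices, per-class and aggregate metrics, and the
# multiclass Matthews correlation coefficient. Zero-denominator conventions
# are explicit throughout: precision, recall and F1 fall back to 0 when their
# denominators vanish, as does MCC.

#' Confusion matrix over known + unknown labels
#'
#' Rows are truth, columns are predictions, in the order
#' `c(vocabulary, unknown)`.
#'
#' @param truth,predicted Equal-length label vectors; every value must lie in
#'   `vocabulary` or equal `unknown`.
#' @param vocabulary Ordered known labels; defaults to the sorted union of
#'   known labels seen in `truth` and `predicted`.
#' @param unknown The reserved unknown label.
#' @return An integer matrix of class `os_confusion` with `dimnames`
#'   `truth` x `predicted`.
#' @export
#' @examples
#' confusion_matrix(c("a", "b", "b"), c("a", "b", "__unknown__"),
#'                  vocabulary = c("a", "b"))
confusion_matrix <- function(truth, predicted, vocabulary = NULL,
                             unknown = unknown_label()) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length")
  }
  if (is.null(vocabulary)) {
    vocabulary <- sort(setdiff(unique(c(truth, predicted)), unknown))
  }
  labels <- c(vocabulary, unknown)
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad) > 0L) {
    abort(sprintf("label(s) outside the vocabulary: %s",
                  paste(sQuote(bad), collapse = ", ")))
  }
  t_f <- factor(truth, levels = labels)
  p_f <- factor(predicted, levels = labels)
  cm <- table(truth = t_f, predicted = p_f)
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(truth = labels, predicted = labels))
  structure(cm, class = c("os_confusion", "matrix"), unknown = unknown)
}

#' @export
print.os_confusion <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @describeIn confusion_matrix Long-format view; `normalize = TRUE` divides
#'   each row by its total (rows with zero support stay zero).
#' @param x An `os_confusion`.
#' @param normalize Row-normalize the counts.
#' @param ... Unused.
#' @method tidy os_confusion
#' @export
tidy.os_confusion <- function(x, normalize = FALSE, ...) {
  m <- unclass(x)
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  tibble(truth = rep(rownames(m), times = ncol(m)),
         predicted = rep(colnames(m), each = nrow(m)),
         value = as.vector(m))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall, F1 and support, plus overall accuracy, macro
#' and support-weighted averages, balanced accuracy (mean recall over classes
#' with support) and the generalized multiclass Matthews correlation
#' coefficient in its covariance form. Conventions: a metric whose denominator
#' is zero is 0; macro averages run over labels that occur in truth or in
#' predictions; weighted averages weight by support over labels with support.
#'
#' AUPRC cannot be derived from counts alone; [evaluation_report()] fills it
#' in from probability outputs.
#'
#' @param cm An [confusion_matrix()] result (any square counts matrix with
#'   dimnames works).
#' @return An object of class `metrics_report`: list with `per_class` (tibble
#'   `label`, `precision`, `recall`, `f1`, `support`), `accuracy`,
#'   `macro_precision/recall/f1`, `weighted_precision/recall/f1`,
#'   `balanced_accuracy`, `mcc`, `auprc_macro` (NA here).
#' @export
classification_metrics <- function(cm) {
  m <- unclass(cm)
  storage.mode(m) <- "double"
  if (!is.matrix(m) || nrow(m) != ncol(m) || sum(m) <= 0) {
    abort("`cm` must be a non-empty square confusion matrix")
  }
  labels <- rownames(m)
  total <- sum(m)
  tp <- diag(m)
  support <- rowSums(m)   # truth counts
  predn <- colSums(m)     # prediction counts
  div0 <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- div0(tp, predn)
  recall <- div0(tp, support)
  f1 <- div0(2 * precision * recall, precision + recall)
  active <- support > 0 | predn > 0
  with_support <- support > 0
  w <- support[with_support] / sum(support[with_support])
  # covariance form of the multiclass MCC
  num <- total * sum(tp) - sum(support * predn)
  den <- sqrt(total^2 - sum(predn^2)) * sqrt(total^2 - sum(support^2))
  mcc <- if (den == 0) 0 else num / den
  structure(list(
    per_class = tibble(label = labels, precision = precision, recall = recall,
                       f1 = f1, support = as.integer(support)),
    accuracy = sum(tp) / total,
    macro_precision = mean(precision[active]),
    macro_recall = mean(recall[active]),
    macro_f1 = mean(f1[active]),
    weighted_precision = sum(precision[with_support] * w),
    weighted_recall = sum(recall[with_support] * w),
    weighted_f1 = sum(f1[with_support] * w),
    balanced_accuracy = mean(recall[with_support]),
    mcc = mcc,
    auprc_macro = NA_real_,
    n = as.integer(total)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d  accuracy %.4f  balanced %.4f  MCC %.4f\n",
              x$n, x$accuracy, x$balanced_accuracy, x$mcc))
  cat(sprintf("  macro P/R/F1: %.4f / %.4f / %.4f   weighted: %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1,
              x$weighted_precision, x$weighted_recall, x$weighted_f1))
  invisible(x)
}

#' @describeIn classification_metrics Per-class tibble.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @describeIn classification_metrics One-row aggregate tibble.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_precision = x$macro_precision, macro_recall = x$macro_recall,
         macro_f1 = x$macro_f1,
         weighted_precision = x$weighted_precision,
         weighted_recall = x$weighted_recall, weighted_f1 = x$weighted_f1,
         balanced_accuracy = x$balanced_accuracy, mcc = x$mcc,
         auprc_macro = x$auprc_macro, n = x$n)
}

#' Full evaluation report for open-set predictions
#'
#' Convenience wrapper: confusion matrix + [classification_metrics()] +
#' (when probability columns are supplied) the macro AUPRC from
#' [roc_pr_curves()].
#'
#' @param truth True labels (known labels or the unknown marker).
#' @param predictions Prediction tibble from [predict.open_set_model()], or a
#'   character vector of predicted labels.
#' @param vocabulary Ordered known labels.
#' @param unknown The reserved unknown label.
#' @return A `metrics_report` with `auprc_macro` filled in when possible, and
#'   the confusion matrix attached as `$confusion`.
#' @export
evaluation_report <- function(truth, predictions, vocabulary = NULL,
                              unknown = unknown_label()) {
  predicted <- if (is.data.frame(predictions)) predictions$predicted
               else predictions
  cm <- confusion_matrix(truth, predicted, vocabulary, unknown)
  rep <- classification_metrics(cm)
  if (is.data.frame(predictions) && "p_unknown" %in% names(predictions)) {
    vocab <- setdiff(rownames(cm), unknown)
    probs <- as.matrix(predictions[c("p_unknown",
                                     paste0("p_class_", seq_along(vocab) - 1L))])
    colnames(probs) <- c(unknown, vocab)
    curves <- roc_pr_curves(truth, probs)
    rep$auprc_macro <- curves$summary$auprc_macro
    rep$curves <- curves
  }
  rep$confusion <- cm
  rep
}
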