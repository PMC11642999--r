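# One-vs-rest ROC and precision-recall curves over the extended label set,
# with a micro-average that pools every (sample, label) decision. Thresholds
# are the unique scores; ROC area is trapezoidal, PR area is the step-wise
# (average-precision) sum with no interpolation.

binary_roc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  # collapse tied scores into one operating point
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  np <- sum(y); nn <- sum(!y)
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp / nn),
         tpr = c(0, tp / np))
}

binary_pr <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; n_pred <- which(last)
  np <- sum(y)
  tibble(threshold = s[last],
         recall = tp / np,
         precision = tp / n_pred)
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

step_auprc <- function(recall, precision) {
  sum(diff(c(0, recall)) * precision)
}

#' ROC and precision-recall curves for open-set probabilities
#'
#' One-vs-rest curves for every label (including the unknown class) plus a
#' micro-average that pools all (sample, label) binary decisions. A label with
#' single-class truth (no positives or no negatives) has no defined curve; it
#' is flagged and excluded from the macro AUPRC.
#'
#' @param truth Label vector.
#' @param probabilities Numeric matrix (or data frame), one column per label,
#'   column names matching the label set in `truth`'s universe; rows should
#'   sum to 1.
#' @return An object of class `os_curves`: list with `roc` (tibble `label`,
#'   `threshold`, `fpr`, `tpr`), `pr` (tibble `label`, `threshold`, `recall`,
#'   `precision`), `auc` (per-label tibble with `auc`, `auprc`, `defined`),
#'   and `summary` (micro AUC and macro AUPRC).
#' @export
roc_pr_curves <- function(truth, probabilities) {
  probs <- as.matrix(probabilities)
  if (is.null(colnames(probs))) {
    abort("`probabilities` must have column names identifying the labels")
  }
  if (nrow(probs) != length(truth)) {
    abort("`truth` and `probabilities` must have the same number of rows")
  }
  labels <- colnames(probs)
  roc_list <- list(); pr_list <- list(); auc_rows <- list()
  for (lab in labels) {
    pos <- truth == lab
    if (all(pos) || !any(pos)) {
      auc_rows[[lab]] <- tibble(label = lab, auc = NA_real_,
                                auprc = NA_real_, defined = FALSE)
      next
    }
    r <- binary_roc(probs[, lab], pos)
    p <- binary_pr(probs[, lab], pos)
    roc_list[[lab]] <- dplyr::mutate(r, label = lab, .before = 1)
    pr_list[[lab]] <- dplyr::mutate(p, label = lab, .before = 1)
    auc_rows[[lab]] <- tibble(label = lab,
                              auc = trapezoid(r$fpr, r$tpr),
                              auprc = step_auprc(p$recall, p$precision),
                              defined = TRUE)
  }
  # micro-average: pool all (sample, label) indicator decisions
  pooled_scores <- as.vector(probs)
  pooled_pos <- as.vector(outer(truth, labels, `==`))
  micro_roc <- binary_roc(pooled_scores, pooled_pos)
  micro_pr <- binary_pr(pooled_scores, pooled_pos)
  roc_list[["micro"]] <- dplyr::mutate(micro_roc, label = "micro", .before = 1)
  pr_list[["micro"]] <- dplyr::mutate(micro_pr, label = "micro", .before = 1)
  auc <- purrr::list_rbind(auc_rows)
  out <- list(
    roc = purrr::list_rbind(roc_list),
    pr = purrr::list_rbind(pr_list),
    auc = auc,
    summary = tibble(
      micro_auc = trapezoid(micro_roc$fpr, micro_roc$tpr),
      micro_auprc = step_auprc(micro_pr$recall, micro_pr$precision),
      auprc_macro = mean(auc$auprc[auc$defined])))
  class(out) <- "os_curves"
  out
}

#' @export
print.os_curves <- function(x, ...) {
  cat(sprintf("<os_curves> %d labels; micro AUC %.4f, macro AUPRC %.4f\n",
              nrow(x$auc), x$summary$micro_auc, x$summary$auprc_macro))
  print(x$auc)
  invisible(x)
}
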