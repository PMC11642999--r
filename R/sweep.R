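# Threshold sweep: the same evaluation repeated across a descending grid of
# rejection thresholds epsilon, reporting the standard column set (accuracy,
# micro-F1, macro and weighted precision/recall/F1).

#' Sweep the rejection threshold
#'
#' Runs the model's decision rule at each threshold (scores and OpenMax
#' probabilities are computed once and re-thresholded) and evaluates against
#' `truth` over the extended label set. The `f1` column is the micro-averaged
#' F1, which for single-label classification equals accuracy; it is emitted
#' so the sweep table carries both conventionally reported columns.
#'
#' @param truth True labels for `activations`' rows.
#' @param activations Activation tibble to predict on.
#' @param model An `open_set_model`; its `decision_mode` is used.
#' @param thresholds Epsilon grid, reported in descending order (default
#'   0.5, 0.4, 0.3, 0.2, 0.1).
#' @param unknown Reserved unknown label.
#' @return A tibble of class `threshold_sweep`, one row per threshold:
#'   `threshold`, `accuracy`, `f1`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `weighted_precision`, `weighted_recall`, `weighted_f1`,
#'   `n_unknown_predicted`.
#' @export
threshold_sweep <- function(truth, activations, model,
                            thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                            unknown = unknown_label()) {
  stopifnot(inherits(model, "open_set_model"))
  if (any(thresholds < 0 | thresholds > 1)) {
    abort("`thresholds` must lie in [0, 1]")
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  z <- activation_matrix(activations)
  mode <- model$config$decision_mode
  scores <- t(apply(z, 1L, recalibrated_scores, model = model))
  probs <- t(apply(z, 1L, openmax_probabilities, model = model))
  rows <- purrr::map(thresholds, function(eps) {
    predicted <- vapply(seq_len(nrow(z)), function(i) {
      if (mode == "score_threshold") {
        predict_score_threshold(scores[i, ], eps, model$vocabulary,
                                unknown = unknown)
      } else {
        predict_openmax(probs[i, ], eps, model$vocabulary, unknown = unknown)
      }
    }, character(1))
    cm <- confusion_matrix(truth, predicted, model$vocabulary, unknown)
    met <- classification_metrics(cm)
    tibble(threshold = eps,
           accuracy = met$accuracy,
           f1 = met$accuracy,  # micro-F1 == accuracy for single-label tasks
           macro_precision = met$macro_precision,
           macro_recall = met$macro_recall,
           macro_f1 = met$macro_f1,
           weighted_precision = met$weighted_precision,
           weighted_recall = met$weighted_recall,
           weighted_f1 = met$weighted_f1,
           n_unknown_predicted = sum(predicted == unknown))
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("threshold_sweep", class(out))
  out
}
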