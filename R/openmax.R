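# The open-set core: mean activation vectors (MAVs), per-class Weibull
# distance tails, score recalibration, and the two rejection procedures —
# a threshold on the maximum recalibrated score, and the OpenMax probability
# computation that redistributes activation mass of atypical samples to an
# explicit unknown class.

#' Configuration for open-set model fitting and prediction
#'
#' @param beta Number of top-ranked classes whose activations OpenMax
#'   down-weights, in `0..M`. `NULL` (default) means all `M` classes — a
#'   neutral choice exposed here rather than guessed.
#' @param tail_size Weibull tail size eta; the per-class effective value is
#'   `min(tail_size, N_c)` (default 20, the conventional meta-recognition
#'   size).
#' @param threshold Rejection threshold epsilon in `[0, 1]` applied by the
#'   decision rule (default 0.1).
#' @param decision_mode `"score_threshold"` rejects when the maximum
#'   recalibrated score `max r_c < epsilon`; `"openmax"` computes OpenMax
#'   probabilities over M+1 classes and rejects when the argmax is the unknown
#'   class or its probability falls below epsilon.
#' @param mav_source `"all_samples"` averages every vector of a class;
#'   `"correct_only"` restricts to vectors whose argmax equals the class (the
#'   convention of the original OpenMax literature).
#' @param location_mode Location handling for the Weibull fit, see
#'   [fit_weibull_tail()].
#' @return An object of class `openmax_config`.
#' @export
openmax_config <- function(beta = NULL, tail_size = 20L, threshold = 0.1,
                           decision_mode = c("score_threshold", "openmax"),
                           mav_source = c("all_samples", "correct_only"),
                           location_mode = c("zero", "tail_min")) {
  decision_mode <- match.arg(decision_mode)
  mav_source <- match.arg(mav_source)
  location_mode <- match.arg(location_mode)
  if (!is.null(beta)) {
    if (!is.numeric(beta) || beta < 0 || beta != trunc(beta)) {
      abort("`beta` must be a nonnegative integer (or NULL for all classes)")
    }
    beta <- as.integer(beta)
  }
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1]")
  check_positive_int(tail_size, "tail_size")
  structure(list(beta = beta, tail_size = as.integer(tail_size),
                 threshold = threshold, decision_mode = decision_mode,
                 mav_source = mav_source, location_mode = location_mode),
            class = "openmax_config")
}

#' Per-class mean activation vectors
#'
#' The MAV of class c is the arithmetic mean of that class's activation
#' vectors; with `mav_source = "correct_only"` only vectors whose argmax
#' (ties to the lowest vocabulary index) is class c qualify.
#'
#' @param activations Activation tibble (`sample_id`, `label`, `a0 ...`).
#' @param vocabulary Ordered known labels; defaults to the sorted unique
#'   labels present (rows labelled with `unknown` are ignored).
#' @param mav_source See [openmax_config()].
#' @param unknown Reserved unknown label to drop before averaging.
#' @return A tibble `label`, `n`, `mav` (list column of M-vectors), ordered by
#'   vocabulary.
#' @export
compute_mavs <- function(activations, vocabulary = NULL,
                         mav_source = c("all_samples", "correct_only"),
                         unknown = unknown_label()) {
  mav_source <- match.arg(mav_source)
  known <- activations[activations$label != unknown, , drop = FALSE]
  if (is.null(vocabulary)) vocabulary <- sort(unique(known$label))
  z <- activation_matrix(known)
  if (ncol(z) < length(vocabulary)) {
    abort("activation dimension is smaller than the vocabulary")
  }
  rows <- purrr::map(vocabulary, function(lab) {
    zc <- z[known$label == lab, , drop = FALSE]
    if (mav_source == "correct_only") {
      pred <- max.col(zc, ties.method = "first")
      zc <- zc[pred == match(lab, vocabulary), , drop = FALSE]
    }
    if (nrow(zc) == 0L) {
      abort(sprintf(
        "cannot build model: class '%s' has no %s records", lab,
        if (mav_source == "correct_only") "correctly classified" else ""))
    }
    tibble(label = lab, n = nrow(zc), mav = list(colMeans(zc)))
  })
  purrr::list_rbind(rows)
}

#' Euclidean distance between an activation vector and a MAV
#'
#' @param vector,mav Numeric vectors of equal length.
#' @return The l2 norm of their difference.
#' @export
#' @examples
#' mav_distance(c(3, 4), c(0, 0))  # 5
mav_distance <- function(vector, mav) {
  if (length(vector) != length(mav)) {
    abort("`vector` and `mav` must have the same length")
  }
  sqrt(sum((vector - mav)^2))
}

#' Fit an open-set model from labelled activations
#'
#' Composes the whole model-building path: MAVs per class, distances of each
#' class's own (qualifying) vectors to its MAV, and a Weibull tail fitted to
#' the `min(tail_size, N_c)` largest of those distances. Deterministic: two
#' builds from the same input serialize identically.
#'
#' @param activations Activation tibble of known-class training samples.
#' @param vocabulary Ordered labels; default sorted unique labels.
#' @param config An [openmax_config()].
#' @param unknown Reserved unknown label (rows so labelled are excluded).
#' @return An object of class `open_set_model` with fields `vocabulary`,
#'   `profiles` (per-class list: `label`, `mav`, `tail`, `n_samples`,
#'   `tail_size`) and `config`.
#' @export
#' @examples
#' acts <- synth_activations(synth_spec(3, per_class_n = 30, seed = 1))
#' model <- fit_open_set_model(acts)
#' model
fit_open_set_model <- function(activations, vocabulary = NULL,
                               config = openmax_config(),
                               unknown = unknown_label()) {
  stopifnot(inherits(config, "openmax_config"))
  mavs <- compute_mavs(activations, vocabulary, config$mav_source,
                       unknown = unknown)
  vocabulary <- mavs$label
  known <- activations[activations$label != unknown, , drop = FALSE]
  z <- activation_matrix(known)
  profiles <- purrr::pmap(mavs, function(label, n, mav) {
    zc <- z[known$label == label, , drop = FALSE]
    if (config$mav_source == "correct_only") {
      pred <- max.col(zc, ties.method = "first")
      zc <- zc[pred == match(label, vocabulary), , drop = FALSE]
    }
    d <- sqrt(rowSums(sweep(zc, 2L, mav)^2))
    eta <- min(config$tail_size, length(d))
    tail <- tryCatch(
      fit_weibull_tail(d, tail_size = eta,
                       location_mode = config$location_mode),
      error = function(e) abort(sprintf(
        "cannot fit Weibull tail for class '%s': %s", label,
        conditionMessage(e))))
    list(label = label, mav = mav, tail = tail, n_samples = n,
         tail_size = as.integer(eta))
  })
  names(profiles) <- vocabulary
  structure(list(vocabulary = vocabulary, profiles = profiles,
                 config = config),
            class = "open_set_model")
}

#' @export
print.open_set_model <- function(x, ...) {
  cat(sprintf("<open_set_model> %d classes, decision '%s', epsilon %g, beta %s\n",
              length(x$vocabulary), x$config$decision_mode,
              x$config$threshold,
              if (is.null(x$config$beta)) "M" else x$config$beta))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_open_set_model Per-class summary: one row per profile with
#'   the Weibull parameters.
#' @param x An `open_set_model`.
#' @param ... Unused.
#' @method tidy open_set_model
#' @export
tidy.open_set_model <- function(x, ...) {
  purrr::map(x$profiles, function(p) {
    tibble(label = p$label, n_samples = p$n_samples, tail_size = p$tail_size,
           shape = p$tail$shape, scale = p$tail$scale,
           location = p$tail$location)
  }) |> purrr::list_rbind()
}

#' @describeIn fit_open_set_model One-row model summary.
#' @method glance open_set_model
#' @export
glance.open_set_model <- function(x, ...) {
  tibble(n_classes = length(x$vocabulary),
         dim = length(x$profiles[[1]]$mav),
         beta = if (is.null(x$config$beta)) length(x$vocabulary)
                else x$config$beta,
         tail_size = x$config$tail_size,
         threshold = x$config$threshold,
         decision_mode = x$config$decision_mode,
         mav_source = x$config$mav_source)
}

#' Recalibrated per-class scores for one activation vector
#'
#' `r_c = 1 - CDF_Weibull(d_c)` where `d_c` is the Euclidean distance to class
#' c's MAV and the CDF is that class's fitted tail. Typical samples score near
#' 1, outliers near 0; `r_c` is nonincreasing in the distance. Computed
#' through the log survival function so extreme distances underflow to 0
#' rather than losing precision.
#'
#' @param vector Activation M-vector.
#' @param model An [fit_open_set_model()] result.
#' @return Named numeric vector of `r_c` in `[0, 1]`, in vocabulary order.
#' @export
recalibrated_scores <- function(vector, model) {
  stopifnot(inherits(model, "open_set_model"))
  vapply(model$profiles, function(p) {
    exp(weibull_log_survival(mav_distance(vector, p$mav), p$tail))
  }, numeric(1))
}

#' Decision rule on recalibrated scores
#'
#' Returns the unknown label when `max(r_c) < threshold`, else the label of
#' the maximising class; ties break to the lowest vocabulary index.
#'
#' @param scores Numeric vector of `r_c` in vocabulary order.
#' @param threshold Rejection threshold epsilon.
#' @param vocabulary Ordered class labels.
#' @param unknown Unknown label to return on rejection.
#' @return A single label string.
#' @export
predict_score_threshold <- function(scores, threshold,
                                    vocabulary = names(scores),
                                    unknown = unknown_label()) {
  if (max(scores) < threshold) unknown else vocabulary[which.max(scores)]
}

#' OpenMax probabilities over M+1 classes
#'
#' Ranks classes by descending activation, then for the top `beta` classes
#' down-weights the activation by `theta = 1 - ((beta - j)/beta) * CDF(d)`,
#' where `CDF` is the class's fitted Weibull CDF at the sample's distance to
#' that class's MAV and `j` is the rank. The mass removed from the known
#' classes, `sum_j a_j (1 - theta_j)`, becomes the activation of a synthetic
#' unknown class (index 0), and a numerically stabilised softmax over the M+1
#' activations yields the probabilities. With `beta = 0` no class is modified
#' and the result reduces to a plain softmax with a constant `e^0` unknown
#' term.
#'
#' The `literal` flag swaps in the multiplier `exp((d/scale)^shape)` in place
#' of the Weibull CDF. That form (an exponential of a positive quantity, so
#' always >= 1 and unbounded) drives `theta` outside `[0, 1]` and is kept only
#' as a diagnostic for comparison; the CDF weighting is the supported
#' procedure.
#'
#' @param vector Activation M-vector.
#' @param model An `open_set_model`.
#' @param beta Override of the config's beta (`NULL` = config, whose `NULL`
#'   means M).
#' @param literal Use the divergent exponential multiplier instead of the
#'   Weibull CDF (diagnostic only).
#' @return Named `(M+1)`-vector of probabilities summing to 1; the first
#'   element is the unknown class.
#' @export
openmax_probabilities <- function(vector, model, beta = NULL, literal = FALSE) {
  stopifnot(inherits(model, "open_set_model"))
  m <- length(model$vocabulary)
  if (is.null(beta)) beta <- model$config$beta
  if (is.null(beta)) beta <- m
  if (beta > m) abort(sprintf("`beta` (%d) cannot exceed M (%d)", beta, m))
  a <- as.double(vector)
  ranks <- order(a, decreasing = TRUE)
  theta <- rep(1, m)
  if (beta > 0) {
    for (j in seq_len(beta)) {
      k <- ranks[j]
      p <- model$profiles[[k]]
      d <- mav_distance(a, p$mav)
      wscore <- if (literal) {
        exp((max(d - p$tail$location, 0) / p$tail$scale)^p$tail$shape)
      } else {
        weibull_cdf(d, p$tail)
      }
      theta[k] <- 1 - ((beta - j) / beta) * wscore
    }
  }
  a_hat <- a * theta
  a0 <- sum(a * (1 - theta))
  v <- c(a0, a_hat)
  e <- exp(v - max(v))
  p <- e / sum(e)
  names(p) <- c(unknown_label(), model$vocabulary)
  p
}

#' Decision rule on OpenMax probabilities
#'
#' Rejects (returns the unknown label) when the maximising index is the
#' unknown class or its probability is below `threshold`; otherwise returns
#' the corresponding vocabulary label. Ties break to the lowest index, i.e.
#' towards the unknown class first.
#'
#' @param probabilities `(M+1)`-vector from [openmax_probabilities()] (unknown
#'   first).
#' @param threshold Rejection threshold epsilon.
#' @param vocabulary Ordered class labels.
#' @param unknown Unknown label to return on rejection.
#' @return A single label string.
#' @export
predict_openmax <- function(probabilities, threshold,
                            vocabulary = names(probabilities)[-1],
                            unknown = unknown_label()) {
  star <- which.max(probabilities)
  if (star == 1L || probabilities[star] < threshold) unknown
  else vocabulary[star - 1L]
}

#' Predict known-or-unknown labels for an activation table
#'
#' Applies the model's decision mode to every row of `newdata` and returns
#' the standard prediction table: the predicted label (possibly the unknown
#' marker), the maximum recalibrated score, and the OpenMax probabilities
#' `p_unknown, p_class_0 ... p_class_{M-1}` (columns indexed in vocabulary
#' order).
#'
#' @param object An `open_set_model`.
#' @param newdata Activation tibble with `sample_id` and `a0 ...` columns.
#' @param threshold Optional override of the config's epsilon.
#' @param decision_mode Optional override of the config's decision mode.
#' @param ... Unused.
#' @return A tibble with one row per sample.
#' @export
predict.open_set_model <- function(object, newdata, threshold = NULL,
                                   decision_mode = NULL, ...) {
  threshold <- threshold %||% object$config$threshold
  decision_mode <- decision_mode %||% object$config$decision_mode
  z <- activation_matrix(newdata)
  m <- length(object$vocabulary)
  res <- purrr::map(seq_len(nrow(z)), function(i) {
    a <- z[i, ]
    r <- recalibrated_scores(a, object)
    p <- openmax_probabilities(a, object)
    pred <- if (decision_mode == "score_threshold") {
      predict_score_threshold(r, threshold, object$vocabulary)
    } else {
      predict_openmax(p, threshold, object$vocabulary)
    }
    c(list(pred = pred, max_score = max(r)), as.list(unname(p)))
  })
  out <- tibble(
    sample_id = if ("sample_id" %in% names(newdata)) newdata$sample_id
                else sprintf("s%05d", seq_len(nrow(z))),
    predicted = vapply(res, function(x) x$pred, character(1)),
    max_score = vapply(res, function(x) x$max_score, numeric(1)))
  probs <- t(vapply(res, function(x)
    unlist(x[-(1:2)], use.names = FALSE), numeric(m + 1L)))
  colnames(probs) <- c("p_unknown", paste0("p_class_", seq_len(m) - 1L))
  dplyr::bind_cols(out, as_tibble(probs))
}

#' Empirical-vs-fitted tail diagnostics
#'
#' For each class: the deciles of the observed distances between that class's
#' samples and its MAV, alongside the fitted Weibull CDF evaluated at those
#' deciles. A well-fitting tail has `fitted_cdf` tracking `empirical_cdf` in
#' the upper deciles (the lower ones lie below the fitted tail's reach when
#' eta < N_c). Feed the result to [autoplot()] for a per-class panel akin to
#' per-species Weibull diagnostic plots.
#'
#' @param model An `open_set_model`.
#' @param activations Activation tibble with true labels (typically the
#'   training set the model was fitted on).
#' @param probs Quantile probabilities (default deciles 0.1 ... 0.9).
#' @return A tibble `label`, `prob`, `distance`, `empirical_cdf`,
#'   `fitted_cdf` of class `tail_diagnostics`.
#' @export
tail_diagnostics <- function(model, activations,
                             probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(model, "open_set_model"))
  z <- activation_matrix(activations)
  out <- purrr::map(model$profiles, function(p) {
    zc <- z[activations$label == p$label, , drop = FALSE]
    if (nrow(zc) == 0L) return(NULL)
    d <- sqrt(rowSums(sweep(zc, 2L, p$mav)^2))
    q <- unname(quantile(d, probs = probs, type = 7))
    tibble(label = p$label, prob = probs, distance = q,
           empirical_cdf = probs, fitted_cdf = weibull_cdf(q, p$tail))
  }) |> purrr::list_rbind()
  class(out) <- c("tail_diagnostics", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
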