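test_that("confusion matrix tallies truth by prediction", {
  cm <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"),
                         vocabulary = c("a", "b"))
  expect_equal(diag(cm)[1:2], c(a = 1L, b = 2L))
  expect_equal(classification_metrics(cm)$accuracy, 1)

  all_unk <- confusion_matrix(c("a", "b"), rep(unknown_label(), 2),
                              vocabulary = c("a", "b"))
  expect_equal(sum(all_unk[, unknown_label()]), 2L)
  expect_equal(sum(all_unk[, c("a", "b")]), 0L)

  expect_error(confusion_matrix("a", "zzz", vocabulary = "a"), "zzz")
  expect_error(confusion_matrix(c("a", "a"), "a", vocabulary = "a"), "length")

  set.seed(71)
  labs <- c(letters[1:4], unknown_label())
  truth <- sample(labs, 200, replace = TRUE)
  pred <- sample(labs, 200, replace = TRUE)
  cm2 <- confusion_matrix(truth, pred, vocabulary = letters[1:4])
  for (i in labs) for (j in labs) {
    expect_equal(cm2[i, j], sum(truth == i & pred == j))
  }
})

test_that("metrics match the independent-formula oracle to 1e-12", {
  # degenerate predictor: everything into one column
  cm <- matrix(c(50, 50, 0, 0), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 0.5)
  expect_equal(met$mcc, 0)

  set.seed(72)
  for (rep in 1:50) {
    m <- matrix(rpois(16, lambda = sample(1:30, 1)), 4, 4,
                dimnames = list(truth = letters[1:4], predicted = letters[1:4]))
    if (sum(m) == 0) m[1, 1] <- 1
    got <- classification_metrics(m)
    want <- oracle_metrics(m)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(unname(got$per_class$precision), want$precision, tolerance = 1e-12)
    expect_equal(unname(got$per_class$recall), want$recall, tolerance = 1e-12)
    expect_equal(unname(got$per_class$f1), want$f1, tolerance = 1e-12)
    expect_equal(got$macro_precision, want$macro_precision, tolerance = 1e-12)
    expect_equal(got$macro_recall, want$macro_recall, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_equal(got$weighted_precision, want$weighted_precision, tolerance = 1e-12)
    expect_equal(got$weighted_recall, want$weighted_recall, tolerance = 1e-12)
    expect_equal(got$weighted_f1, want$weighted_f1, tolerance = 1e-12)
    expect_equal(got$balanced_accuracy, want$balanced_accuracy, tolerance = 1e-12)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    # identity: support-weighted recall equals accuracy
    expect_equal(got$weighted_recall, got$accuracy, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to sample order", {
  set.seed(73)
  labs <- letters[1:3]
  truth <- sample(labs, 100, replace = TRUE)
  pred <- sample(labs, 100, replace = TRUE)
  g1 <- glance(classification_metrics(confusion_matrix(truth, pred, labs)))
  perm <- sample(100)
  g2 <- glance(classification_metrics(
    confusion_matrix(truth[perm], pred[perm], labs)))
  expect_equal(g1, g2)
})

test_that("ROC/PR curves hit the analytic limits", {
  # perfect separation: every one-vs-rest AUC and AUPRC is 1
  truth <- rep(c("a", "b", "c"), each = 10)
  probs <- matrix(0.05, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  probs[cbind(1:30, match(truth, c("a", "b", "c")))] <- 0.9
  cv <- roc_pr_curves(truth, probs)
  expect_true(all(cv$auc$auc == 1))
  expect_true(all(cv$auc$auprc == 1))
  expect_equal(cv$summary$micro_auc, 1)

  # chance-level scores: micro AUC near one half
  set.seed(74)
  n <- 2000
  truth2 <- sample(c("a", "b"), n, replace = TRUE)
  p <- runif(n)
  probs2 <- cbind(a = p, b = 1 - p)
  cv2 <- roc_pr_curves(truth2, probs2)
  expect_lt(abs(cv2$summary$micro_auc - 0.5), 0.05)

  # single-class truth: that curve is flagged undefined and excluded
  cv3 <- roc_pr_curves(rep("a", 5), cbind(a = runif(5), b = runif(5)))
  expect_false(cv3$auc$defined[cv3$auc$label == "b"])
  expect_false(cv3$auc$defined[cv3$auc$label == "a"])
})

test_that("trapezoidal AUC equals the exhaustive pairwise oracle", {
  set.seed(75)
  truth <- sample(c("a", "b", "c"), 50, replace = TRUE)
  raw <- matrix(runif(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  probs <- raw / rowSums(raw)
  cv <- roc_pr_curves(truth, probs)
  for (lab in c("a", "b", "c")) {
    expect_equal(cv$auc$auc[cv$auc$label == lab],
                 oracle_auc(probs[, lab], truth == lab), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(76)
  truth <- sample(c("a", "b"), 80, replace = TRUE)
  score <- runif(80) + 0.5 * (truth == "a")
  cv <- roc_pr_curves(truth, cbind(a = score, b = 1 - score))
  ref <- suppressMessages(as.numeric(pROC::auc(truth == "a", score)))
  expect_equal(cv$auc$auc[cv$auc$label == "a"], ref, tolerance = 1e-12)
})

test_that("evaluation report wires counts and probabilities together", {
  spec <- synth_spec(3, per_class_n = 30, separation = 6, seed = 81)
  model <- fit_open_set_model(synth_activations(spec))
  te <- dplyr::bind_rows(
    synth_activations(synth_spec(3, per_class_n = 10, separation = 6,
                                 seed = 82)),
    dplyr::select(synth_ood_activations(spec, 20), -source))
  pr <- predict(model, te)
  rep <- evaluation_report(te$label, pr, vocabulary = model$vocabulary)
  expect_s3_class(rep$confusion, "os_confusion")
  expect_equal(nrow(rep$confusion), 4)   # 3 known + unknown
  expect_false(is.na(rep$auprc_macro))
  expect_equal(rep$n, 50L)
  # probabilities in the prediction table are a valid simplex row-wise
  pm <- as.matrix(pr[c("p_unknown", paste0("p_class_", 0:2))])
  expect_equal(unname(rowSums(pm)), rep(1, 50), tolerance = 1e-9)
  expect_true(all(pm >= 0))
})

test_that("threshold sweep reports the descending grid consistently", {
  spec <- synth_spec(4, per_class_n = 40, separation = 6, seed = 91)
  model <- fit_open_set_model(synth_activations(spec))
  te <- dplyr::bind_rows(
    synth_activations(synth_spec(4, per_class_n = 10, separation = 6,
                                 seed = 92)),
    dplyr::select(synth_ood_activations(spec, 40), -source))
  sw <- threshold_sweep(te$label, te, model)
  expect_equal(sw$threshold, c(0.5, 0.4, 0.3, 0.2, 0.1))
  # unknown predictions nondecreasing in epsilon (= reverse of sweep order)
  expect_true(all(diff(rev(sw$n_unknown_predicted)) >= 0))

  # epsilon = 0 rejects nothing in score_threshold mode and reproduces the
  # closed-set argmax accuracy
  sw0 <- threshold_sweep(te$label, te, model, thresholds = 0)
  expect_equal(sw0$n_unknown_predicted, 0L)
  z <- as.matrix(te[paste0("a", 0:3)])
  argmax_r <- apply(z, 1, function(v) {
    r <- recalibrated_scores(v, model)
    model$vocabulary[which.max(r)]
  })
  expect_equal(sw0$accuracy, mean(argmax_r == te$label), tolerance = 1e-12)

  # each sweep row equals an independent per-threshold evaluation
  for (i in c(1, 5)) {
    pr_i <- predict(model, te, threshold = sw$threshold[i])
    rep_i <- evaluation_report(te$label, pr_i$predicted,
                               vocabulary = model$vocabulary)
    expect_equal(sw$accuracy[i], rep_i$accuracy, tolerance = 1e-12)
    expect_equal(sw$macro_f1[i], rep_i$macro_f1, tolerance = 1e-12)
  }
  expect_error(threshold_sweep(te$label, te, model, thresholds = c(0.5, 2)),
               "0, 1")
})
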