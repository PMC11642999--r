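# Shared small fixture: a 3-class model with hand-set geometry.
toy_model <- function(decision_mode = "score_threshold", threshold = 0.1,
                      beta = NULL) {
  spec <- synth_spec(3, per_class_n = 40, separation = 6, seed = 42)
  fit_open_set_model(synth_activations(spec),
                     config = openmax_config(beta = beta,
                                             decision_mode = decision_mode,
                                             threshold = threshold))
}

test_that("MAVs are plain per-class means", {
  df <- tibble::tibble(sample_id = c("a", "b", "c"),
                       label = c("x", "y", "y"),
                       a0 = c(1, 0, 2), a1 = c(2, 2, 0), a2 = c(3, 1, 1))
  mavs <- compute_mavs(df)
  expect_equal(mavs$mav[[which(mavs$label == "x")]], c(a0 = 1, a1 = 2, a2 = 3))
  expect_equal(mavs$mav[[which(mavs$label == "y")]], c(a0 = 1, a1 = 1, a2 = 1))

  set.seed(55)
  z <- matrix(rnorm(100 * 4), 100, 4)
  df2 <- tibble::tibble(sample_id = sprintf("s%03d", 1:100), label = "only")
  df2[paste0("a", 0:3)] <- as.data.frame(z)
  got <- compute_mavs(df2, vocabulary = "only")$mav[[1]]
  want <- rep(0, 4)
  for (i in 1:100) for (j in 1:4) want[j] <- want[j] + z[i, j] / 100
  expect_equal(unname(got), want, tolerance = 1e-12)

  # correct_only drops misclassified vectors and errors when none qualify
  df3 <- tibble::tibble(sample_id = c("a", "b"), label = c("x", "y"),
                        a0 = c(5, 5), a1 = c(0, 0))
  expect_error(compute_mavs(df3, vocabulary = c("x", "y"),
                            mav_source = "correct_only"), "'y'")
})

test_that("distance to MAV is the Euclidean norm", {
  expect_equal(mav_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mav_distance(c(3, 4), c(0, 0)), 5)
  set.seed(9)
  v <- rnorm(10); m <- rnorm(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (v[i] - m[i])^2
  expect_equal(mav_distance(v, m), sqrt(acc), tolerance = 1e-14)
  expect_error(mav_distance(1:3, 1:4), "length")
})

test_that("recalibrated scores follow the Weibull survival function", {
  model <- toy_model()
  p1 <- model$profiles[[1]]
  r_at_mav <- recalibrated_scores(p1$mav, model)
  expect_equal(unname(r_at_mav[1]), 1)          # zero distance, location 0
  far <- p1$mav + 1e3
  expect_equal(max(recalibrated_scores(far, model)), 0, tolerance = 1e-12)

  # hand computation through distances -> CDF -> r for a hand-set model
  hand <- structure(list(
    vocabulary = c("u", "v", "w"),
    profiles = list(
      u = list(label = "u", mav = c(4, 0, 0),
               tail = weibull_tail(2, 1.5), n_samples = 10L, tail_size = 5L),
      v = list(label = "v", mav = c(0, 4, 0),
               tail = weibull_tail(3, 2.0), n_samples = 10L, tail_size = 5L),
      w = list(label = "w", mav = c(0, 0, 4),
               tail = weibull_tail(1.2, 0.8, location = 1),
               n_samples = 10L, tail_size = 5L)),
    config = openmax_config()), class = "open_set_model")
  a <- c(3, 1, 0.5)
  d <- c(sqrt(1 + 1 + 0.25), sqrt(9 + 9 + 0.25), sqrt(9 + 1 + 12.25))
  want <- c(exp(-(d[1] / 1.5)^2), exp(-(d[2] / 2)^3),
            exp(-(((d[3] - 1) / 0.8)^1.2)))
  expect_equal(unname(recalibrated_scores(a, hand)), want, tolerance = 1e-12)

  # monotone: r nonincreasing along a ray away from the MAV
  ray <- seq(0, 8, by = 0.25)
  rs <- vapply(ray, function(t)
    recalibrated_scores(p1$mav + t * c(1, rep(0, 2)), model)[1], numeric(1))
  expect_true(all(diff(rs) <= 1e-12))
})

test_that("score-threshold decision rule, including ties", {
  expect_equal(predict_score_threshold(c(0.05, 0.03), 0.1, c("a", "b")),
               unknown_label())
  expect_equal(predict_score_threshold(c(0.9, 0.2), 0.5, c("a", "b")), "a")
  expect_equal(predict_score_threshold(c(0.4, 0.4), 0.1, c("a", "b")), "a")
})

test_that("OpenMax reduces to softmax at beta = 0", {
  model <- toy_model()
  a <- c(5, 1, 0.3)
  p <- openmax_probabilities(a, model, beta = 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[1]), 1 / (1 + sum(exp(a))), tolerance = 1e-12)
  expect_equal(unname(p[-1]), exp(a) / (1 + sum(exp(a))), tolerance = 1e-12)

  # all CDF values 0 (sample at every MAV's location support edge is
  # impossible; instead: distances below every location) ==> same as beta=0
  loc_model <- model
  for (k in 1:3) loc_model$profiles[[k]]$tail$location <- 1e6
  p_loc <- openmax_probabilities(a, loc_model, beta = 3)
  expect_equal(unname(p_loc), unname(p), tolerance = 1e-12)
})

test_that("OpenMax matches the line-by-line transcription oracle", {
  set.seed(202)
  n_checked <- 0
  for (m in c(2L, 3L, 10L)) {
    spec <- synth_spec(m, per_class_n = 30, separation = 5,
                       seed = 1000L + m)
    model <- fit_open_set_model(synth_activations(spec))
    mavs <- lapply(model$profiles, `[[`, "mav")
    tails <- lapply(model$profiles, `[[`, "tail")
    for (beta in unique(c(0L, 1L, m))) {
      for (rep in 1:15) {
        a <- rnorm(m, sd = 4) + sample(c(0, 5), m, replace = TRUE)
        got <- openmax_probabilities(a, model, beta = beta)
        want <- oracle_openmax(a, mavs, tails, beta)
        expect_equal(unname(got), want, tolerance = 1e-9)
        expect_equal(sum(got), 1, tolerance = 1e-9)
        expect_true(all(got >= 0))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 100)
  expect_error(openmax_probabilities(rnorm(3), toy_model(), beta = 4), "exceed")
})

test_that("the literal printed multiplier is available but flagged divergent", {
  # hand-set mild tails keep the exponential finite for inspection
  hand <- structure(list(
    vocabulary = c("u", "v"),
    profiles = list(
      u = list(label = "u", mav = c(2, 0), tail = weibull_tail(1.1, 4),
               n_samples = 10L, tail_size = 5L),
      v = list(label = "v", mav = c(0, 2), tail = weibull_tail(1.1, 4),
               n_samples = 10L, tail_size = 5L)),
    config = openmax_config()), class = "open_set_model")
  a <- c(1.5, 0.5)
  lit <- openmax_probabilities(a, hand, beta = 2, literal = TRUE)
  std <- openmax_probabilities(a, hand, beta = 2)
  expect_equal(sum(lit), 1, tolerance = 1e-9)  # still a softmax
  expect_false(isTRUE(all.equal(unname(lit), unname(std))))
  # the literal multiplier is exp of a positive quantity, >= 1 everywhere,
  # so the down-weighted theta exceeds the CDF form's damping: the unknown
  # mass under `literal` is at least the standard form's
  expect_gte(lit[[1]], std[[1]])
})

test_that("OpenMax decision rule rejects on unknown argmax or low confidence", {
  v <- c("a", "b")
  expect_equal(predict_openmax(c(0.6, 0.3, 0.1), 0.0, v), unknown_label())
  expect_equal(predict_openmax(c(0.1, 0.7, 0.2), 0.5, v), "a")
  expect_equal(predict_openmax(c(0.1, 0.45, 0.45), 0.5, v), unknown_label())
})

test_that("model building composes mavs + per-class tails deterministically", {
  spec <- synth_spec(10, per_class_n = 50, separation = 6, seed = 7)
  acts <- synth_activations(spec)
  model <- fit_open_set_model(acts, config = openmax_config(tail_size = 20))
  expect_length(model$profiles, 10)
  # tail fitted on the 20 largest within-class distances: sorting oracle
  z <- as.matrix(acts[paste0("a", 0:9)])
  for (k in c(1, 5, 10)) {
    p <- model$profiles[[k]]
    zc <- z[acts$label == p$label, , drop = FALSE]
    d <- sqrt(rowSums(sweep(zc, 2, p$mav)^2))
    top <- sort(d, decreasing = TRUE)[1:20]
    refit <- fit_weibull_tail(top, tail_size = 20)
    expect_equal(p$tail$shape, refit$shape)
    expect_equal(p$tail$scale, refit$scale)
  }

  # degenerate class sizes are refused: one record cannot carry a tail
  tiny <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         label = c("x", "x", "x", "y"),
                         a0 = c(1, 2, 4, 0), a1 = c(0, 1, 0.5, 5))
  expect_error(fit_open_set_model(tiny), "'y'")
  # and an all-equal distance tail is a degenerate-tail error
  sym <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        label = c("x", "x", "y", "y"),
                        a0 = c(1, 3, 0, 0), a1 = c(0, 0, 2, 4))
  expect_error(fit_open_set_model(sym), "degenerate")

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_open_set_model(model, f1)
  write_open_set_model(fit_open_set_model(acts,
    config = openmax_config(tail_size = 20)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("serialized models round-trip to identical predictions", {
  model <- toy_model()
  path <- tempfile(fileext = ".json")
  write_open_set_model(model, path)
  back <- read_open_set_model(path)
  expect_equal(back$vocabulary, model$vocabulary)
  te <- synth_activations(synth_spec(3, per_class_n = 5, separation = 6,
                                     seed = 77))
  expect_equal(predict(back, te), predict(model, te), tolerance = 1e-15)
  # re-serialization is bit-stable
  path2 <- tempfile(fileext = ".json")
  write_open_set_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rejection counts are monotone in the threshold in both modes", {
  spec <- synth_spec(5, per_class_n = 40, separation = 4, seed = 31)
  model_s <- fit_open_set_model(synth_activations(spec))
  te <- dplyr::bind_rows(
    synth_activations(synth_spec(5, per_class_n = 10, separation = 4,
                                 seed = 32)),
    dplyr::select(synth_ood_activations(spec, 30), -source))
  for (mode in c("score_threshold", "openmax")) {
    counts <- vapply(c(0, 0.1, 0.3, 0.5, 0.9), function(eps) {
      pr <- predict(model_s, te, threshold = eps, decision_mode = mode)
      sum(pr$predicted == unknown_label())
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("tail diagnostics track the fit and survive a round-trip", {
  # dim 2: the distance of an isotropic 2-D Gaussian to its centre is exactly
  # Rayleigh, i.e. Weibull with shape 2, so the fit limit is achievable
  spec <- synth_spec(1, dim = 2, per_class_n = 5000, separation = 0, seed = 61)
  acts <- synth_activations(spec)
  model <- fit_open_set_model(acts,
    config = openmax_config(tail_size = 5000L))
  diag <- tail_diagnostics(model, acts)
  expect_equal(nrow(diag), 9)
  # with the tail equal to the full sample the fitted CDF approximates the
  # empirical CDF at every decile
  expect_lt(max(abs(diag$fitted_cdf - diag$empirical_cdf)), 0.05)

  path <- tempfile(fileext = ".json")
  write_open_set_model(model, path)
  diag2 <- tail_diagnostics(read_open_set_model(path), acts)
  expect_equal(diag$fitted_cdf, diag2$fitted_cdf, tolerance = 1e-14)

  m3 <- toy_model()
  d3 <- tail_diagnostics(m3, synth_activations(synth_spec(3, per_class_n = 40,
    separation = 6, seed = 42)))
  expect_equal(length(unique(d3$label)), 3)
})

test_that("tidy and glance summarise fitted models", {
  model <- toy_model()
  td <- tidy(model)
  expect_equal(nrow(td), 3)
  expect_true(all(c("label", "shape", "scale", "location") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_classes, 3)
  expect_equal(gl$decision_mode, "score_threshold")
})
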