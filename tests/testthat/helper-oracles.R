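# Independent reference implementations used as oracles. Each is a direct,
# loop-level transcription of the defining procedure, deliberately sharing no
# code with the package internals.

# OpenMax probabilities, straight transcription of the published procedure:
# sort activations, scale the top-beta classes by one minus the rank-weighted
# Weibull CDF of the distance to the class mean, collect the removed mass as
# the unknown activation, softmax over M+1.
oracle_openmax <- function(a, mavs, tails, beta) {
  m <- length(a)
  ranks <- order(a, decreasing = TRUE)
  theta <- rep(1, m)
  if (beta > 0) {
    for (j in 1:beta) {
      k <- ranks[j]
      d <- 0
      for (t in seq_along(a)) d <- d + (a[t] - mavs[[k]][t])^2
      d <- sqrt(d)
      tl <- tails[[k]]
      x <- d - tl$location
      cdf <- if (x <= 0) 0 else 1 - exp(-((x / tl$scale)^tl$shape))
      theta[k] <- 1 - ((beta - j) / beta) * cdf
    }
  }
  a_hat <- numeric(m)
  for (k in 1:m) a_hat[k] <- a[k] * theta[k]
  a0 <- 0
  for (k in 1:m) a0 <- a0 + a[k] * (1 - theta[k])
  v <- c(a0, a_hat)
  e <- exp(v)
  e / sum(e)
}

# Per-class metrics by explicit tallying; MCC via the indicator-matrix
# correlation definition (expand the confusion matrix back into samples,
# one-hot encode truth and prediction, and correlate), which is a different
# route than the confusion-matrix covariance formula.
oracle_metrics <- function(cm) {
  labels <- rownames(cm)
  k <- length(labels)
  truth <- c(); pred <- c()
  for (i in 1:k) for (j in 1:k) {
    n <- cm[i, j]
    if (n > 0) { truth <- c(truth, rep(i, n)); pred <- c(pred, rep(j, n)) }
  }
  n <- length(truth)
  prec <- rec <- f1 <- sup <- prd <- numeric(k)
  for (c in 1:k) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    sup[c] <- sum(truth == c)
    prd[c] <- sum(pred == c)
  }
  active <- sup > 0 | prd > 0
  ws <- sup > 0
  X <- matrix(0, n, k); Y <- matrix(0, n, k)
  for (s in 1:n) { X[s, truth[s]] <- 1; Y[s, pred[s]] <- 1 }
  cov2 <- function(A, B) {
    tot <- 0
    for (c in 1:k) {
      tot <- tot + sum((A[, c] - mean(A[, c])) * (B[, c] - mean(B[, c])))
    }
    tot / n
  }
  den <- sqrt(cov2(X, X) * cov2(Y, Y))
  list(accuracy = sum(truth == pred) / n,
       precision = prec, recall = rec, f1 = f1, support = sup,
       macro_precision = mean(prec[active]),
       macro_recall = mean(rec[active]),
       macro_f1 = mean(f1[active]),
       weighted_precision = sum(prec[ws] * sup[ws]) / sum(sup[ws]),
       weighted_recall = sum(rec[ws] * sup[ws]) / sum(sup[ws]),
       weighted_f1 = sum(f1[ws] * sup[ws]) / sum(sup[ws]),
       balanced_accuracy = mean(rec[ws]),
       mcc = if (den == 0) 0 else cov2(X, Y) / den)
}

# dhash / ahash recomputed bit by bit from the stated definition.
oracle_hash_bits <- function(image, algorithm) {
  h <- dim(image)[1]; w <- dim(image)[2]
  g <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    g[i, j] <- 0.299 * image[i, j, 1] + 0.587 * image[i, j, 2] +
      0.114 * image[i, j, 3]
  }
  resize <- function(m, th, tw) {
    out <- matrix(0, th, tw); cnt <- matrix(0, th, tw)
    for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
      bi <- floor((i - 1) * th / nrow(m)) + 1
      bj <- floor((j - 1) * tw / ncol(m)) + 1
      out[bi, bj] <- out[bi, bj] + m[i, j]
      cnt[bi, bj] <- cnt[bi, bj] + 1
    }
    out / cnt
  }
  bits <- integer(0)
  if (algorithm == "dhash") {
    r <- resize(g, 8, 9)
    for (i in 1:8) for (j in 1:8) bits <- c(bits, as.integer(r[i, j] > r[i, j + 1]))
  } else {
    r <- resize(g, 8, 8)
    mu <- mean(r)
    for (i in 1:8) for (j in 1:8) bits <- c(bits, as.integer(r[i, j] >= mu))
  }
  bits
}

oracle_bits_to_hex <- function(bits) {
  hex <- ""
  for (q in seq(1, 64, by = 4)) {
    v <- bits[q] * 8 + bits[q + 1] * 4 + bits[q + 2] * 2 + bits[q + 3]
    hex <- paste0(hex, sprintf("%x", v))
  }
  hex
}

# O(n^2) duplicate grouping by repeated set merging.
oracle_dup_groups <- function(ids, bitmat, max_hamming) {
  n <- length(ids)
  groups <- as.list(seq_len(n))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sum(bitmat[i, ] != bitmat[j, ]) <= max_hamming) {
      gi <- which(vapply(groups, function(g) i %in% g, logical(1)))
      gj <- which(vapply(groups, function(g) j %in% g, logical(1)))
      if (gi != gj) {
        groups[[gi]] <- c(groups[[gi]], groups[[gj]])
        groups[[gj]] <- NULL
      }
    }
  }
  out <- lapply(groups[lengths(groups) >= 2], function(g) sort(ids[g]))
  out[order(vapply(out, `[`, character(1), 1))]
}

# Affine augmentation applied pixel by pixel from an independently composed
# matrix (same stated convention: rotation %*% x-shear(tan) %*% zoom about
# the centre, translation, then horizontal flip; inverse map, nearest
# neighbour, clamp to the frame).
oracle_augment <- function(image, draws) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- draws$theta; sh <- draws$shear; z <- draws$zoom
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shm <- matrix(c(1, 0, tan(sh), 1), 2, 2)
  a <- rot %*% shm %*% (z * diag(2))
  ainv <- solve(a)
  out <- image
  for (yo in 1:h) for (xo in 1:w) {
    xf <- if (draws$flip) w + 1 - xo else xo
    dx <- xf - cx - draws$tx * w
    dy <- yo - cy - draws$ty * h
    xs <- ainv[1, 1] * dx + ainv[1, 2] * dy + cx
    ys <- ainv[2, 1] * dx + ainv[2, 2] * dy + cy
    xi <- min(max(floor(xs + 0.5), 1), w)
    yi <- min(max(floor(ys + 0.5), 1), h)
    out[yo, xo, ] <- image[yi, xi, ]
  }
  out
}

# ROC AUC as the Mann-Whitney U-statistic (probability a positive outscores
# a negative, ties counting one half).
oracle_auc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# Weibull log-likelihood grid search (location zero).
oracle_weibull_grid <- function(x, shapes, scales) {
  best <- c(NA, NA); best_ll <- -Inf
  for (k in shapes) for (s in scales) {
    ll <- sum(log(k / s) + (k - 1) * log(x / s) - (x / s)^k)
    if (ll > best_ll) { best_ll <- ll; best <- c(k, s) }
  }
  list(shape = best[1], scale = best[2], loglik = best_ll)
}

weibull_loglik <- function(x, shape, scale) {
  sum(log(shape / scale) + (shape - 1) * log(x / scale) - (x / scale)^shape)
}

random_hex_hashes <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c(0:9, letters[1:6]), 16, replace = TRUE), collapse = "")
  }, character(1))
}

hex_to_bitrow <- function(hex) {
  v <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  as.integer(unlist(lapply(v, function(n) bitwAnd(n %/% c(8L, 4L, 2L, 1L), 1L))))
}
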