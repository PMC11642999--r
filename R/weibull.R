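# Weibull tail models of within-class distances. The open-set machinery rests
# on the extreme-value view: the largest distances between a class's own
# samples and its mean activation vector are summarised by a two-parameter
# Weibull (optionally translated by a location), and the fitted CDF converts
# a new sample's distance into an outlier probability.

#' Construct a Weibull tail model
#'
#' Mostly produced by [fit_weibull_tail()]; exposed so hand-set tails can be
#' used in tests and toy examples. The CDF is
#' `1 - exp(-(((d - location) / scale)^shape))` for `d > location` and 0
#' otherwise.
#'
#' @param shape,scale Positive Weibull parameters.
#' @param location Nonnegative shift of the support (default 0).
#' @param tail_size,n_fit Bookkeeping: number of tail points used and total
#'   distances offered (optional).
#' @return An object of class `weibull_tail`.
#' @export
weibull_tail <- function(shape, scale, location = 0, tail_size = NA_integer_,
                         n_fit = NA_integer_) {
  if (!is.finite(shape) || shape <= 0) abort("`shape` must be positive")
  if (!is.finite(scale) || scale <= 0) abort("`scale` must be positive")
  if (!is.finite(location) || location < 0) {
    abort("`location` must be nonnegative")
  }
  structure(list(shape = shape, scale = scale, location = location,
                 tail_size = as.integer(tail_size), n_fit = as.integer(n_fit)),
            class = "weibull_tail")
}

#' @export
print.weibull_tail <- function(x, ...) {
  cat(sprintf("<weibull_tail> shape %.4g, scale %.4g, location %.4g (eta = %s)\n",
              x$shape, x$scale, x$location,
              ifelse(is.na(x$tail_size), "?", x$tail_size)))
  invisible(x)
}

#' Weibull CDF of a tail model
#'
#' @param distance Numeric vector of distances.
#' @param tail A [weibull_tail()] object.
#' @return CDF values in `[0, 1]`; 0 at or below the location.
#' @export
#' @examples
#' t <- weibull_tail(shape = 2, scale = 3)
#' weibull_cdf(c(0, 3, 6), t)  # 0, 1 - exp(-1), 1 - exp(-4)
weibull_cdf <- function(distance, tail) {
  stopifnot(inherits(tail, "weibull_tail"))
  x <- pmax(distance - tail$location, 0)
  -expm1(-(x / tail$scale)^tail$shape)
}

# log survival function, exact for extreme distances
weibull_log_survival <- function(distance, tail) {
  x <- pmax(distance - tail$location, 0)
  -(x / tail$scale)^tail$shape
}

#' Fit a Weibull model to the largest distances
#'
#' Selects the `tail_size` largest of the supplied distances, fixes the
#' location (0 by default; `"tail_min"` uses `(1 - 1e-6) * min(tail)` so every
#' tail point stays inside the support), and estimates shape and scale by
#' maximum likelihood. The shape solves the profile-likelihood equation
#' `1/k + mean(log x) - sum(x^k log x) / sum(x^k) = 0`, which is strictly
#' decreasing in `k`; a safeguarded Newton iteration (bisection fallback
#' inside a sign-changing bracket) converges to tolerance 1e-10 within 200
#' iterations from a method-of-moments start. The scale is then
#' `mean(x^k)^(1/k)`.
#'
#' @param distances Nonnegative numeric vector, at least `tail_size` long.
#' @param tail_size Number of largest distances to fit on (eta >= 2). The
#'   conventional meta-recognition default used by [fit_open_set_model()] is
#'   `min(20, N_c)`.
#' @param location_mode `"zero"` (default) or `"tail_min"`.
#' @return A [weibull_tail()] with fitting metadata.
#' @export
#' @examples
#' set.seed(1)
#' fit_weibull_tail(rweibull(500, 2, 3), tail_size = 500)
fit_weibull_tail <- function(distances, tail_size = min(20L, length(distances)),
                             location_mode = c("zero", "tail_min")) {
  location_mode <- match.arg(location_mode)
  if (!is.numeric(tail_size) || tail_size < 2) {
    abort("`tail_size` (eta) must be at least 2")
  }
  tail_size <- as.integer(tail_size)
  distances <- as.double(distances)
  if (any(!is.finite(distances)) || any(distances < 0)) {
    abort("`distances` must be finite and nonnegative")
  }
  if (length(distances) < tail_size) {
    abort(sprintf("need at least eta = %d distances, got %d", tail_size,
                  length(distances)))
  }
  tl <- sort(distances, decreasing = TRUE)[seq_len(tail_size)]
  if (diff(range(tl)) == 0) {
    abort("degenerate tail: all selected distances are equal")
  }
  loc <- switch(location_mode, zero = 0, tail_min = (1 - 1e-6) * min(tl))
  x <- tl - loc
  if (any(x <= 0)) abort("tail values must exceed the location")
  fit <- weibull_profile_mle(x)
  weibull_tail(fit[["shape"]], fit[["scale"]], location = loc,
               tail_size = tail_size, n_fit = length(distances))
}

# Profile-likelihood MLE for the two-parameter Weibull. Values are rescaled
# by their maximum so x^k cannot overflow for large shapes.
weibull_profile_mle <- function(x, tol = 1e-10, max_iter = 200L) {
  m <- max(x)
  y <- x / m
  lx <- log(x)
  mlx <- mean(lx)
  g <- function(k) {
    wk <- y^k
    1 / k + mlx - sum(wk * lx) / sum(wk)
  }
  gprime <- function(k) {
    wk <- y^k
    s0 <- sum(wk); s1 <- sum(wk * lx); s2 <- sum(wk * lx^2)
    -1 / k^2 - (s2 * s0 - s1^2) / s0^2
  }
  # method-of-moments start (Justus approximation)
  cv <- stats::sd(x) / mean(x)
  k <- if (is.finite(cv) && cv > 0) cv^-1.086 else 1
  k <- min(max(k, 1e-3), 1e3)
  # establish a sign-changing bracket: g is strictly decreasing
  lo <- k; hi <- k
  while (g(lo) < 0 && lo > 1e-8) lo <- lo / 2
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (g(lo) < 0 || g(hi) > 0) abort("Weibull MLE failed to bracket the shape")
  for (i in seq_len(max_iter)) {
    gk <- g(k)
    if (abs(gk) < tol) break
    if (gk > 0) lo <- k else hi <- k
    step <- gk / gprime(k)
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi) {
      k_new <- (lo + hi) / 2  # safeguard: bisect when Newton leaves the bracket
    }
    if (abs(k_new - k) < tol * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  scale <- m * mean(y^k)^(1 / k)
  c(shape = k, scale = scale)
}
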