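# Synthetic activation-vector generators. These emulate the geometry of a
# well-trained closed-set classifier's logit space: each known class forms an
# isotropic Gaussian cluster around a scaled one-hot mean, with a single
# `separation` knob controlling how far apart the clusters sit (in units of
# the within-class spread).

#' Specification for synthetic activation data
#'
#' Bundles the parameters of the synthetic activation generators into a
#' validated object. Class `c` of `n_classes` is drawn from an isotropic
#' Gaussian centred at `separation * spread * e_c`, where `e_c` is the c-th
#' standard basis vector of `dim`-dimensional space, and `spread` is the
#' within-class standard deviation of every coordinate. `separation` is
#' therefore the distance between a class mean and the origin, measured in
#' spread units; the distance between any two class means is
#' `separation * spread * sqrt(2)`.
#'
#' @param n_classes Number of known classes, M (positive integer).
#' @param dim Activation dimension; defaults to `n_classes`, and must be at
#'   least `n_classes` so one-hot class means exist.
#' @param per_class_n Samples drawn per class.
#' @param separation Distance of each class mean from the origin in spread
#'   units (nonnegative).
#' @param spread Within-class standard deviation (positive).
#' @param ood_mode How [synth_ood_activations()] places out-of-distribution
#'   samples: `"shifted_cluster"` (a coherent Gaussian cluster equidistant
#'   from every known mean), `"uniform_box"` (coordinates uniform over the
#'   known-activation range), or `"low_margin"` (noisy midpoints between pairs
#'   of class means).
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   output.
#' @param labels Optional character vector of class labels (length
#'   `n_classes`); defaults to `"class_01" ...`.
#'
#' @return An object of class `synth_spec`.
#' @export
#' @examples
#' synth_spec(n_classes = 3, per_class_n = 5, separation = 6, seed = 1)
synth_spec <- function(n_classes,
                       dim = n_classes,
                       per_class_n = 50L,
                       separation = 6,
                       spread = 1,
                       ood_mode = c("shifted_cluster", "uniform_box", "low_margin"),
                       seed = 1L,
                       labels = NULL) {
  check_positive_int(n_classes, "n_classes")
  check_positive_int(dim, "dim")
  check_positive_int(per_class_n, "per_class_n")
  ood_mode <- match.arg(ood_mode)
  if (!is.numeric(separation) || separation < 0) {
    abort("`separation` must be a nonnegative number")
  }
  if (!is.numeric(spread) || spread <= 0) abort("`spread` must be positive")
  if (dim < n_classes) {
    abort(sprintf(
      "invalid spec: `dim` (%d) must be >= `n_classes` (%d) for one-hot class means",
      dim, n_classes))
  }
  if (is.null(labels)) {
    labels <- sprintf("class_%02d", seq_len(n_classes))
  } else if (length(labels) != n_classes || anyDuplicated(labels)) {
    abort("`labels` must be `n_classes` distinct strings")
  }
  structure(
    list(n_classes = as.integer(n_classes), dim = as.integer(dim),
         per_class_n = as.integer(per_class_n), separation = separation,
         spread = spread, ood_mode = ood_mode, seed = as.integer(seed),
         labels = labels),
    class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d classes x %d/class in %d dims; separation %g, spread %g, ood '%s', seed %d\n",
    x$n_classes, x$per_class_n, x$dim, x$separation, x$spread, x$ood_mode,
    x$seed))
  invisible(x)
}

# class means as a matrix (rows = classes)
class_means <- function(spec) {
  mu <- matrix(0, spec$n_classes, spec$dim)
  mu[cbind(seq_len(spec$n_classes), seq_len(spec$n_classes))] <-
    spec$separation * spec$spread
  mu
}

#' Generate a synthetic known-class activation set
#'
#' Draws `per_class_n` activation vectors per class from the Gaussian cluster
#' model described in [synth_spec()]. Labels are exactly balanced and the
#' output is deterministic under the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with columns `sample_id`, `label` and activation columns
#'   `a0 ... a{dim-1}`, one row per sample.
#' @export
#' @examples
#' acts <- synth_activations(synth_spec(3, per_class_n = 4, seed = 7))
#' dplyr::count(acts, label)
synth_activations <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  mu <- class_means(spec)
  with_seed(spec$seed, {
    rows <- purrr::map(seq_len(spec$n_classes), function(c) {
      z <- matrix(rnorm(spec$per_class_n * spec$dim, sd = spec$spread),
                  spec$per_class_n, spec$dim)
      sweep(z, 2L, mu[c, ], `+`)
    })
    z <- do.call(rbind, rows)
    out <- tibble(
      sample_id = sprintf("s%05d", seq_len(nrow(z))),
      label = rep(spec$labels, each = spec$per_class_n))
    out[activation_cols(spec$dim)] <- as.data.frame(z)
    out
  })
}

#' Generate out-of-distribution activation vectors
#'
#' Emits `n` activation vectors that do not belong to any known class, labelled
#' with the reserved unknown marker. Three placement modes are available (see
#' [synth_spec()]); `shifted_cluster` is the default because it mirrors the
#' realistic scenario of coherent non-target classes (other insect species)
#' rather than white noise. A `composition` vector splits the samples into
#' provenance groups (e.g. `c(33, 34, 33)` for three source insect sets); in
#' `shifted_cluster` mode each group receives its own cluster centre.
#'
#' @param spec A [synth_spec()]; the same spec used for the known set, so the
#'   OOD geometry is placed relative to the known clusters.
#' @param n Number of OOD samples (positive).
#' @param composition Optional positive integer vector summing to `n`, sizes
#'   of provenance groups. Default: one group of `n`.
#' @param unknown Label string for the OOD records.
#' @return A tibble like [synth_activations()] plus a `source` column naming
#'   the provenance group.
#' @export
synth_ood_activations <- function(spec, n, composition = NULL,
                                  unknown = unknown_label()) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n)) {
    abort("`n` must be a positive integer")
  }
  n <- as.integer(n)
  if (is.null(composition)) composition <- n
  composition <- as.integer(composition)
  if (any(composition < 1) || sum(composition) != n) {
    abort("`composition` must be positive integers summing to `n`")
  }
  mu <- class_means(spec)
  g <- length(composition)
  with_seed(derive_seed(spec$seed, "ood"), {
    draw_group <- function(gi, ng) {
      switch(spec$ood_mode,
        shifted_cluster = {
          # centre on the all-ones diagonal: equidistant from every one-hot
          # class mean; successive groups move further out along it
          centre <- rep(spec$separation * spec$spread * (1 + (gi - 1) / (2 * g)),
                        spec$dim)
          sweep(matrix(rnorm(ng * spec$dim, sd = spec$spread), ng, spec$dim),
                2L, centre, `+`)
        },
        uniform_box = {
          known <- activation_matrix(synth_activations(spec))
          lo <- apply(known, 2L, min)
          hi <- apply(known, 2L, max)
          u <- matrix(runif(ng * spec$dim), ng, spec$dim)
          sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
        },
        low_margin = {
          i <- sample.int(spec$n_classes, ng, replace = TRUE)
          off <- sample.int(spec$n_classes - 1L, ng, replace = TRUE)
          j <- 1L + (i - 1L + off) %% spec$n_classes
          (mu[i, , drop = FALSE] + mu[j, , drop = FALSE]) / 2 +
            matrix(rnorm(ng * spec$dim, sd = spec$spread), ng, spec$dim)
        })
    }
    z <- do.call(rbind, purrr::map(seq_len(g), function(gi)
      draw_group(gi, composition[gi])))
    out <- tibble(
      sample_id = sprintf("ood%05d", seq_len(n)),
      label = unknown,
      source = rep(sprintf("ood_template_%d", seq_len(g)), composition))
    out[activation_cols(spec$dim)] <- as.data.frame(z)
    out
  })
}
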