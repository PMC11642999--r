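# Corpus engineering: stratified splitting, balance planning, and the
# geometric augmentation used to synthesise images for under-represented
# classes.

#' Stratified train/validation/test split
#'
#' Splits a manifest class by class, first holding out a test fraction
#' (`1 - outer_ratio`) and then carving a validation fraction
#' (`1 - inner_ratio`) out of the remainder, so the default 0.8/0.8 ratios
#' give the conventional 64% / 16% / 20% partition. Within each class the ids
#' are shuffled by a seeded generator; the test count is `round(0.2 * n_c)`
#' (half up) taken from the end of the shuffle, then the validation count by
#' the same rule from what remains. For class sizes divisible by 25 the
#' 64/16/20 identity is exact.
#'
#' @param manifest Data frame with columns `image_id` and `label`; every class
#'   must have at least one row.
#' @param outer_ratio Fraction kept out of the test set (default 0.8).
#' @param inner_ratio Fraction of the remainder kept out of validation
#'   (default 0.8).
#' @param seed Integer seed; identical seed gives an identical assignment.
#' @return A tibble `image_id`, `label`, `partition` with `partition` one of
#'   `"train"`, `"validation"`, `"test"`; one row per manifest row.
#' @export
#' @examples
#' m <- tibble::tibble(image_id = sprintf("i%02d", 1:25), label = "a")
#' dplyr::count(stratified_split(m, seed = 1), partition)
stratified_split <- function(manifest, outer_ratio = 0.8, inner_ratio = 0.8,
                             seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("image_id", "label") %in% names(manifest)))
  if (nrow(manifest) == 0L) abort("`manifest` is empty")
  if (anyDuplicated(manifest$image_id)) {
    abort("`manifest$image_id` must be unique")
  }
  if (outer_ratio <= 0 || outer_ratio >= 1 || inner_ratio <= 0 ||
      inner_ratio >= 1) {
    abort("split ratios must lie strictly between 0 and 1")
  }
  with_seed(seed, {
    parts <- manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_map(function(df, key) {
        ids <- df$image_id[sample.int(nrow(df))]
        n <- length(ids)
        n_test <- round_half_up((1 - outer_ratio) * n)
        rest <- n - n_test
        n_val <- round_half_up((1 - inner_ratio) * rest)
        part <- rep("train", n)
        if (n_test > 0) part[(n - n_test + 1L):n] <- "test"
        if (n_val > 0) part[(rest - n_val + 1L):rest] <- "validation"
        tibble(image_id = ids, label = key$label, partition = part)
      })
    dplyr::bind_rows(parts)
  })
}

#' Plan class-balancing augmentation
#'
#' For each class, the deficit is the number of synthetic images needed to
#' reach `target`; classes already at or above target need none. The plan is
#' pure arithmetic — executing it is [balance_corpus()]'s job.
#'
#' @param counts Named integer vector or a data frame with columns `label` and
#'   `n` (as from `dplyr::count()`), current images per class.
#' @param target Desired images per class (>= 1).
#' @return A tibble `label`, `count`, `target`, `deficit`.
#' @export
#' @examples
#' plan_balance(c("Aedes aegypti" = 219, "Culex quinquefasciatus" = 500), 500)
plan_balance <- function(counts, target) {
  check_positive_int(target, "target")
  if (is.data.frame(counts)) {
    stopifnot(all(c("label", "n") %in% names(counts)))
    counts <- setNames(counts$n, counts$label)
  }
  tibble(label = names(counts),
         count = as.integer(counts),
         target = as.integer(target),
         deficit = pmax(0L, as.integer(target) - as.integer(counts)))
}

#' Augmentation parameters
#'
#' Magnitudes of the random affine augmentation applied when balancing
#' classes: rotation up to ±20 degrees (larger rotations would distort the
#' anatomical cues — wing position, antennae orientation — that species
#' identification relies on), width/height shifts and zoom at ±20%, shear at
#' ±0.20 radians, horizontal flips, and nearest-edge fill for pixels mapped
#' from outside the frame. The shift is a fraction of the image dimension and
#' zoom is multiplicative in `[1 - zoom_frac, 1 + zoom_frac]`.
#'
#' @param rotation_max_deg Max rotation magnitude in degrees.
#' @param shift_frac Max translation as a fraction of width/height.
#' @param shear_max Max shear angle in radians.
#' @param zoom_frac Zoom half-range (must be < 1).
#' @param horizontal_flip Flip with probability 0.5 when `TRUE`.
#' @param fill_mode Only `"nearest"` is supported.
#' @param seed Base seed used by [balance_corpus()] to derive per-image draws.
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(rotation_max_deg = 20, shift_frac = 0.20,
                                shear_max = 0.20, zoom_frac = 0.20,
                                horizontal_flip = TRUE,
                                fill_mode = "nearest", seed = 1L) {
  vals <- c(rotation_max_deg, shift_frac, shear_max, zoom_frac)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("augmentation magnitudes must be nonnegative")
  }
  if (zoom_frac >= 1) abort("`zoom_frac` must be < 1")
  fill_mode <- match.arg(fill_mode, "nearest")
  structure(list(rotation_max_deg = rotation_max_deg, shift_frac = shift_frac,
                 shear_max = shear_max, zoom_frac = zoom_frac,
                 horizontal_flip = isTRUE(horizontal_flip),
                 fill_mode = fill_mode, seed = as.integer(seed)),
            class = "augmentation_params")
}

# Sample one transform's draws in a fixed order.
sample_augmentation_draws <- function(params, draw_seed) {
  with_seed(draw_seed, list(
    theta = runif(1, -params$rotation_max_deg, params$rotation_max_deg) * pi / 180,
    tx = runif(1, -params$shift_frac, params$shift_frac),
    ty = runif(1, -params$shift_frac, params$shift_frac),
    shear = runif(1, -params$shear_max, params$shear_max),
    zoom = runif(1, 1 - params$zoom_frac, 1 + params$zoom_frac),
    flip = params$horizontal_flip && runif(1) < 0.5))
}

# 2x2 linear part of the forward transform: rotation %*% shear %*% zoom,
# acting on (x, y) offsets from the image centre. x = column, y = row, pixel
# centres at integer coordinates.
augmentation_linear <- function(theta, shear, zoom) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sh <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  rot %*% sh %*% (zoom * diag(2))
}

#' Apply one random affine augmentation to an image
#'
#' Samples a single transform — rotation, shear, zoom and translation about
#' the image centre, optionally followed by a horizontal flip — and applies it
#' by inverse mapping with nearest-neighbour resampling; output pixels whose
#' source falls outside the frame take the nearest edge pixel. With all
#' magnitudes zero and flipping disabled the output equals the input exactly.
#'
#' @param image `H x W x 3` (or `H x W`) numeric array.
#' @param params An [augmentation_params()] object.
#' @param draw_seed Integer seed for this draw; [balance_corpus()] derives one
#'   per synthesised image.
#' @param draws Optional pre-sampled draw list (internal/testing use);
#'   overrides `draw_seed`.
#' @return An array of the same shape and range as the input.
#' @export
augment_image <- function(image, params = augmentation_params(),
                          draw_seed = 1L, draws = NULL) {
  stopifnot(inherits(params, "augmentation_params"), is.numeric(image))
  if (is.null(draws)) draws <- sample_augmentation_draws(params, draw_seed)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  a <- augmentation_linear(draws$theta, draws$shear, draws$zoom)
  ainv <- solve(a)
  tx <- draws$tx * w; ty <- draws$ty * h
  # output grid; undo the flip first, then the affine part
  xo <- matrix(seq_len(w), h, w, byrow = TRUE)
  yo <- matrix(seq_len(h), h, w)
  if (draws$flip) xo <- w + 1 - xo
  dx <- xo - cx - tx
  dy <- yo - cy - ty
  xs <- ainv[1, 1] * dx + ainv[1, 2] * dy + cx
  ys <- ainv[2, 1] * dx + ainv[2, 2] * dy + cy
  # nearest-neighbour with nearest-edge fill
  xi <- pmin(pmax(round_half_up(xs), 1), w)
  yi <- pmin(pmax(round_half_up(ys), 1), h)
  out <- image
  if (length(d) == 2L) {
    out[] <- image[cbind(as.vector(yi), as.vector(xi))]
  } else {
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch]
      o <- plane
      o[] <- plane[cbind(as.vector(yi), as.vector(xi))]
      out[, , ch] <- o
    }
  }
  out
}

#' Execute a balancing plan on a corpus
#'
#' Synthesises each class's deficit by cycling through that class's images in
#' manifest order and applying [augment_image()] with a per-image derived
#' seed. Afterwards every class count equals `max(original, target)`.
#'
#' @param corpus A corpus list (`images` + `manifest`), e.g. from
#'   [synth_image_corpus()].
#' @param plan A plan tibble from [plan_balance()].
#' @param params An [augmentation_params()]; its `seed` drives all draws.
#' @return The corpus with augmented images appended; new manifest rows carry
#'   ids `aug_<label>_<i>`.
#' @export
balance_corpus <- function(corpus, plan, params = augmentation_params()) {
  stopifnot(is.list(corpus), is.data.frame(plan))
  manifest <- corpus$manifest
  new_imgs <- list()
  new_rows <- list()
  for (r in seq_len(nrow(plan))) {
    lab <- plan$label[r]; deficit <- plan$deficit[r]
    if (deficit == 0L) next
    src <- manifest$image_id[manifest$label == lab]
    if (length(src) == 0L) abort(sprintf("no source images for class '%s'", lab))
    for (i in seq_len(deficit)) {
      sid <- src[(i - 1L) %% length(src) + 1L]
      id <- sprintf("aug_%s_%04d", lab, i)
      ds <- derive_seed(params$seed, paste0("augment/", lab, "/", i))
      new_imgs[[id]] <- augment_image(corpus$images[[sid]], params,
                                      draw_seed = ds)
      new_rows[[id]] <- tibble(image_id = id, label = lab, path = NA_character_)
    }
  }
  corpus$images <- c(corpus$images, new_imgs)
  corpus$manifest <- dplyr::bind_rows(manifest, purrr::list_rbind(new_rows))
  corpus
}
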