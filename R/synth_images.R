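# Toy image corpus: each class is a deterministic geometric template (a
# distinct axis-aligned shape at a class-indexed position and colour) plus
# optional Gaussian pixel noise. The corpus has no pretensions to realism; it
# exists so the dedup / split / balance / extract stages run end-to-end on
# data whose structure is fully known.

#' Deterministic class templates for the toy image corpus
#'
#' One RGB template per label: shape type cycles through disc, horizontal bar,
#' vertical bar, cross, square, ring, and two diagonals, with the shape centre
#' and channel intensities indexed by the class position. Templates are pure
#' functions of `(labels, image_size)`.
#'
#' @param labels Character vector of class labels.
#' @param image_size `c(H, W)`, both at least 16.
#' @return A named list of `H x W x 3` numeric arrays with entries in 0..255.
#' @export
class_templates <- function(labels, image_size = c(32L, 32L)) {
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (h < 16L || w < 16L) abort("`image_size` must be at least 16 x 16")
  shapes <- c("disc", "hbar", "vbar", "cross", "square", "ring", "diag", "antidiag")
  out <- purrr::imap(setNames(seq_along(labels), labels), function(k, lab) {
    img <- array(32, dim = c(h, w, 3L))
    # class-indexed centre, kept away from the border
    cy <- 1L + ((k * 7L) %% (h - 12L)) + 6L
    cx <- 1L + ((k * 11L) %% (w - 12L)) + 6L
    r <- 5L
    y <- matrix(seq_len(h), h, w)
    x <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- switch(shapes[(k - 1L) %% length(shapes) + 1L],
      disc   = (y - cy)^2 + (x - cx)^2 <= r^2,
      hbar   = abs(y - cy) <= 2L & abs(x - cx) <= r,
      vbar   = abs(x - cx) <= 2L & abs(y - cy) <= r,
      cross  = (abs(y - cy) <= 1L & abs(x - cx) <= r) |
               (abs(x - cx) <= 1L & abs(y - cy) <= r),
      square = abs(y - cy) <= r & abs(x - cx) <= r,
      ring   = {
        d2 <- (y - cy)^2 + (x - cx)^2
        d2 <= r^2 & d2 >= (r - 2L)^2
      },
      diag     = abs((y - cy) - (x - cx)) <= 1L & abs(y - cy) <= r,
      antidiag = abs((y - cy) + (x - cx)) <= 1L & abs(y - cy) <= r)
    fg <- c(224, 96 + 16 * ((k - 1L) %% 8L), 255 - 16 * ((k - 1L) %% 8L))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- fg[ch]
      img[, , ch] <- plane
    }
    img
  })
  out
}

#' Generate an imbalanced toy image corpus
#'
#' Renders `class_counts[label]` images per class from that class's template
#' plus i.i.d. Gaussian pixel noise, rounded and clamped to 8-bit range. A
#' manifest tibble accompanies the pixel data; when `dir` is given the images
#' are also written as PNG files and the manifest's `path` column points at
#' them.
#'
#' @param class_counts Named integer vector or list, label -> count (all
#'   counts >= 1).
#' @param image_size `c(H, W)` with H, W >= 16.
#' @param noise_sd Standard deviation of the additive pixel noise, in
#'   intensity units (0 gives the noiseless template).
#' @param seed Integer seed; same arguments + seed give identical pixels.
#' @param dir Optional directory to write PNGs into.
#' @return A list with `images` (named list of `H x W x 3` arrays, names =
#'   image ids), `manifest` (tibble `image_id`, `label`, `path`), and
#'   `templates`.
#' @export
#' @examples
#' corpus <- synth_image_corpus(c(a = 2, b = 3), noise_sd = 4, seed = 1)
#' corpus$manifest
synth_image_corpus <- function(class_counts, image_size = c(32L, 32L),
                               noise_sd = 8, seed = 1L, dir = NULL) {
  counts <- unlist(class_counts)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("`class_counts` must be named by label")
  }
  if (any(counts < 1) || any(counts != trunc(counts))) {
    abort("all class counts must be positive integers")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  tmpl <- class_templates(names(counts), image_size)
  h <- dim(tmpl[[1]])[1]; w <- dim(tmpl[[1]])[2]
  images <- list()
  ids <- character(0); labs <- character(0)
  with_seed(seed, {
    for (lab in names(counts)) {
      for (i in seq_len(counts[[lab]])) {
        id <- sprintf("%s_%04d", lab, i)
        px <- tmpl[[lab]]
        if (noise_sd > 0) {
          px <- px + array(rnorm(h * w * 3L, sd = noise_sd), dim = c(h, w, 3L))
        }
        images[[id]] <- pmin(pmax(round(px), 0), 255)
        ids <- c(ids, id); labs <- c(labs, lab)
      }
    }
  })
  paths <- rep(NA_character_, length(ids))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(ids, ".png"))
    purrr::walk2(images, paths, function(img, p)
      png::writePNG(img / 255, target = p))
  }
  list(images = images,
       manifest = tibble(image_id = ids, label = labs, path = paths),
       templates = tmpl)
}

#' Toy activation extractor
#'
#' Stand-in for a trained network's logit head: component `c` of the returned
#' vector is the negative mean squared pixel difference between the image and
#' template `c`, divided by 255^2 so logits are O(1) and softmax stays in a
#' benign numerical range. An image identical to template `c` scores exactly 0
#' on component `c`, the maximum attainable.
#'
#' @param image `H x W x 3` numeric array.
#' @param templates List of arrays with the same dimensions as `image`.
#' @return Numeric vector, one component per template (names preserved).
#' @export
toy_extract <- function(image, templates) {
  d <- dim(image)
  vapply(templates, function(t) {
    if (!identical(dim(t), d)) {
      abort("template dimensions must match the image")
    }
    -mean((image - t)^2) / 255^2
  }, numeric(1))
}

#' Extract activation vectors for a whole corpus
#'
#' Runs [toy_extract()] over every image in a corpus manifest and returns the
#' standard activation table consumed by the open-set stages.
#'
#' @param corpus A list as returned by [synth_image_corpus()] (fields
#'   `images`, `manifest`, `templates`).
#' @param templates Optional template list; defaults to the corpus's own.
#' @return A tibble `sample_id`, `label`, `a0 ...`.
#' @export
toy_extract_corpus <- function(corpus, templates = corpus$templates) {
  acts <- t(vapply(corpus$manifest$image_id,
                   function(id) toy_extract(corpus$images[[id]], templates),
                   numeric(length(templates))))
  out <- tibble(sample_id = corpus$manifest$image_id,
                label = corpus$manifest$label)
  out[activation_cols(length(templates))] <- as.data.frame(unname(acts))
  out
}
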