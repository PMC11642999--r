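# Perceptual hashing for near-duplicate image detection. Two classic 64-bit
# hashes are provided: the difference hash (dhash) and the average hash
# (ahash). Hashes are stored as 16-character lowercase hex strings; bit order
# is row-major with the most significant bit first.

luma <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Block-mean downscale of a matrix to th x tw: source pixel i maps to target
# bin floor((i-1)*t/S) + 1; each target cell is the mean of its source block.
block_resize <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  if (h < th || w < tw) abort("image too small to hash (need >= 9 x 9 pixels)")
  ri <- floor((seq_len(h) - 1) * th / h) + 1
  ci <- floor((seq_len(w) - 1) * tw / w) + 1
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri, th), tabulate(ci, tw))
  sums / cnt
}

bits_to_hex <- function(bits) {
  stopifnot(length(bits) == 64L)
  nib <- matrix(as.integer(bits), nrow = 4L)
  paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
}

hex_to_bits <- function(hex) {
  hex <- tolower(sub("^0x", "", hex))
  hex <- formatC(hex, width = 16, flag = "0")
  if (nchar(hex) != 16L || grepl("[^0-9a-f]", hex)) {
    abort(sprintf("not a 64-bit hex hash: '%s'", hex))
  }
  v <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  as.integer(unlist(lapply(v, function(n) bitwAnd(n %/% c(8L, 4L, 2L, 1L), 1L))))
}

#' Perceptual hash of an image
#'
#' Computes a 64-bit perceptual fingerprint such that visually similar images
#' (small shifts, noise, re-encodes) have small Hamming distance.
#'
#' `dhash` converts to grayscale with luma weights (0.299, 0.587, 0.114),
#' block-averages to a 9-wide by 8-tall grid, and emits one bit per
#' horizontally adjacent pair (1 when the left cell is brighter than the
#' right). `ahash` block-averages the grayscale image to 8 x 8 and emits one
#' bit per cell (1 when the cell is at least the grid mean). Bits are packed
#' row-major, most significant bit first, into a 16-hex-digit string.
#'
#' @param image `H x W x 3` numeric array (0..255), at least 9 x 9 pixels, or
#'   a path to a PNG file.
#' @param algorithm `"dhash"` (default) or `"ahash"`.
#' @param image_id Identifier recorded in the output; defaults to the file
#'   path when `image` is a path.
#' @return A one-row tibble `image_id`, `hash` (hex string), `algorithm`.
#' @export
#' @examples
#' img <- class_templates("a", c(32, 32))[[1]]
#' phash(img, "dhash", image_id = "a")
phash <- function(image, algorithm = c("dhash", "ahash"), image_id = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- image
    px <- tryCatch(png::readPNG(image), error = function(e)
      abort(sprintf("cannot decode image file '%s': %s", image,
                    conditionMessage(e))))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    image <- px[, , 1:3, drop = FALSE] * 255
  }
  if (is.null(image_id)) image_id <- NA_character_
  g <- luma(image)
  bits <- if (algorithm == "dhash") {
    r <- block_resize(g, 8L, 9L)
    as.integer(t(r[, 1:8] > r[, 2:9]))
  } else {
    r <- block_resize(g, 8L, 8L)
    as.integer(t(r >= mean(r)))
  }
  tibble(image_id = image_id, hash = bits_to_hex(bits), algorithm = algorithm)
}

#' Hash every image in a corpus
#'
#' @param corpus A corpus as from [synth_image_corpus()], or a named list of
#'   image arrays.
#' @inheritParams phash
#' @return A tibble of hash records, one row per image.
#' @export
phash_corpus <- function(corpus, algorithm = c("dhash", "ahash")) {
  algorithm <- match.arg(algorithm)
  images <- if (!is.null(corpus$images)) corpus$images else corpus
  purrr::imap(images, function(img, id) phash(img, algorithm, image_id = id)) |>
    purrr::list_rbind()
}

#' Hamming distance between 64-bit hex hashes
#'
#' @param a,b Hex hash strings (vectorised; recycled to a common length).
#' @return Integer vector of differing-bit counts (0..64).
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) sum(hex_to_bits(a[i]) != hex_to_bits(b[i])),
         integer(1))
}

#' Group near-duplicate images by hash distance
#'
#' Forms the transitive closure of all pairs at Hamming distance at most
#' `max_hamming`: if A~B and B~C then A, B, C share a group even when A and C
#' are farther apart. Within each group the lexicographically smallest
#' `image_id` is flagged as the keeper (the copy to retain); singletons are
#' omitted entirely.
#'
#' @param hashes Tibble with columns `image_id`, `hash` and (optionally)
#'   `algorithm`; mixing algorithms is an error since their distances are not
#'   comparable.
#' @param max_hamming Distance threshold (default 5 of 64 bits, common
#'   perceptual-hash practice).
#' @return Tibble `group_id`, `image_id`, `keeper` (logical), ordered by group
#'   then id.
#' @export
find_duplicates <- function(hashes, max_hamming = 5L) {
  stopifnot(is.data.frame(hashes), all(c("image_id", "hash") %in% names(hashes)))
  if ("algorithm" %in% names(hashes) &&
      length(unique(hashes$algorithm)) > 1L) {
    abort("all hash records must use the same algorithm")
  }
  if (max_hamming < 0 || max_hamming > 64) {
    abort("`max_hamming` must be in 0..64")
  }
  n <- nrow(hashes)
  if (n == 0L) {
    return(tibble(group_id = integer(), image_id = character(),
                  keeper = logical()))
  }
  bits <- do.call(rbind, lapply(hashes$hash, hex_to_bits))
  # union-find over pairs within threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    di <- bits[(i + 1L):n, , drop = FALSE]
    hd <- rowSums(di != matrix(bits[i, ], nrow(di), 64L, byrow = TRUE))
    for (j in which(hd <= max_hamming)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- split(hashes$image_id, root)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) {
    return(tibble(group_id = integer(), image_id = character(),
                  keeper = logical()))
  }
  grp <- lapply(unname(grp), sort)
  grp <- grp[order(vapply(grp, `[`, character(1), 1L))]
  purrr::imap(grp, function(ids, k) {
    tibble(group_id = as.integer(k), image_id = ids, keeper = ids == ids[1L])
  }) |>
    purrr::list_rbind()
}
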