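# Internal helpers shared across modules.

#' Default label for samples outside the known vocabulary
#'
#' The reserved string used to mark out-of-vocabulary ("unknown") samples in
#' activation tables, predictions and confusion matrices. Every function that
#' deals with unknowns takes an `unknown_label` argument defaulting to this.
#'
#' @return A length-one character vector.
#' @export
#' @examples
#' unknown_label()
unknown_label <- function() "__unknown__"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generators route through this so identical
# (spec, seed) gives byte-identical output regardless of ambient RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero ("round half up" for nonnegative x). Used for all
# split-count arithmetic so that 20% of 25 is exactly 5 and 20% of 26 is 5.
round_half_up <- function(x) floor(x + 0.5)

# Derive a child seed from a root seed and a stage name; stable across runs
# and independent of stage execution order. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) * 131L
  as.integer((as.double(seed) + h) %% 2147483629)
}

# Names of activation columns a0 .. a{M-1} (matches the on-disk dialect).
activation_cols <- function(m) paste0("a", seq_len(m) - 1L)

# Extract the activation matrix from an activation tibble; columns a0.. in
# numeric order. Errors if none present or entries are not finite.
activation_matrix <- function(df) {
  cols <- grep("^a[0-9]+$", names(df), value = TRUE)
  if (length(cols) == 0L) {
    abort("no activation columns (a0, a1, ...) found in the input table")
  }
  cols <- cols[order(as.integer(sub("^a", "", cols)))]
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) abort("activation values must be finite")
  m
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != trunc(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s", name,
                  deparse(substitute(x))))
  }
  invisible(as.integer(x))
}

# Tiny FNV-1a (32-bit) over raw bytes; used for run-manifest checksums.
# Arithmetic kept in doubles below 2^53: the xor only touches the low byte
# and the modular product is split into 16-bit halves.
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + (h %% 65536) * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

fnv1a32_file <- function(path) {
  fnv1a32(readBin(path, what = "raw", n = file.info(path)$size))
}
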