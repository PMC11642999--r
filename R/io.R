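# On-disk formats. Activation tables travel as delimited text (TSV by
# default) with header `sample_id  label  a0 ... a{M-1}` and floats at 9
# significant digits; models as a single JSON document with floats at full
# precision so a write/read round-trip is bit-stable.

delim_for <- function(format = c("tsv", "csv")) {
  switch(match.arg(format), tsv = "\t", csv = ",")
}

#' Write / read activation tables
#'
#' @param activations Activation tibble (`sample_id`, `label`, `a0 ...`).
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `write_activations()` returns `path` invisibly; `read_activations()`
#'   returns a tibble with activation columns as doubles.
#' @export
write_activations <- function(activations, path, format = c("tsv", "csv")) {
  df <- activations
  acols <- grep("^a[0-9]+$", names(df), value = TRUE)
  df[acols] <- lapply(df[acols], function(x) formatC(x, digits = 9, format = "g"))
  readr::write_delim(df, path, delim = delim_for(format))
  invisible(path)
}

#' @rdname write_activations
#' @export
read_activations <- function(path, format = c("tsv", "csv")) {
  if (!file.exists(path)) abort(sprintf("activation file not found: '%s'", path))
  df <- readr::read_delim(path, delim = delim_for(format),
                          show_col_types = FALSE, progress = FALSE)
  acols <- grep("^a[0-9]+$", names(df), value = TRUE)
  df[acols] <- lapply(df[acols], as.double)
  df
}

#' Serialize an open-set model to JSON
#'
#' One JSON document holding the vocabulary, each class's MAV, Weibull
#' parameters, sample count and tail size, and the configuration. Numbers are
#' written at full precision; `read_open_set_model()` restores an identical
#' model.
#'
#' @param model An `open_set_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_open_set_model <- function(model, path) {
  stopifnot(inherits(model, "open_set_model"))
  doc <- list(
    vocabulary = model$vocabulary,
    profiles = purrr::map(model$profiles, function(p) list(
      mav = p$mav,
      weibull = list(shape = p$tail$shape, scale = p$tail$scale,
                     location = p$tail$location),
      n_samples = p$n_samples, tail_size = p$tail_size)),
    config = list(
      beta = model$config$beta, tail_size = model$config$tail_size,
      threshold = model$config$threshold,
      decision_mode = model$config$decision_mode,
      mav_source = model$config$mav_source,
      location_mode = model$config$location_mode))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_open_set_model
#' @export
read_open_set_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: '%s'", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- openmax_config(
    beta = doc$config$beta, tail_size = doc$config$tail_size,
    threshold = doc$config$threshold,
    decision_mode = doc$config$decision_mode,
    mav_source = doc$config$mav_source,
    location_mode = doc$config$location_mode %||% "zero")
  profiles <- purrr::imap(doc$profiles, function(p, lab) list(
    label = lab, mav = as.double(p$mav),
    tail = weibull_tail(p$weibull$shape, p$weibull$scale, p$weibull$location,
                        tail_size = p$tail_size, n_fit = NA_integer_),
    n_samples = as.integer(p$n_samples), tail_size = as.integer(p$tail_size)))
  structure(list(vocabulary = doc$vocabulary, profiles = profiles,
                 config = cfg),
            class = "open_set_model")
}

#' Write a prediction table
#'
#' Columns: `sample_id`, `predicted`, `max_score`, `p_unknown`,
#' `p_class_0 ...` as produced by [predict.open_set_model()].
#'
#' @param predictions Prediction tibble.
#' @param path Output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "csv")) {
  readr::write_delim(predictions, path, delim = delim_for(format))
  invisible(path)
}

#' Write a manifest / split assignment / dedup report as TSV
#'
#' Thin wrappers fixing the column layouts of the pipeline's small artifacts.
#'
#' @param x The tibble to write.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_artifact <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write / read a balancing plan as JSON (label -> deficit)
#'
#' @param plan Plan tibble from [plan_balance()].
#' @param path File path.
#' @return `path` / a named integer vector of deficits.
#' @export
write_balance_plan <- function(plan, path) {
  jsonlite::write_json(as.list(setNames(plan$deficit, plan$label)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_balance_plan
#' @export
read_balance_plan <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
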