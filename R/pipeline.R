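# Orchestration: a flat, validated configuration and a stage runner that
# binds the synthetic generators, corpus engineering, model fitting and
# evaluation into one reproducible workflow. Every stage writes its artifacts
# atomically (temp file + rename) into the output directory, derives its own
# seed from the root seed and the stage name (so stage order cannot change
# the draws), and the run ends with a manifest recording the configuration
# hash and per-artifact checksums.

pipeline_defaults <- function() {
  list(
    out_dir = "openmosq_run",
    seed = 1L,
    format = "tsv",
    log_level = "info",
    # synthetic activations
    n_classes = 10L, dim = NULL, per_class_n = 50L,
    separation = 6, spread = 1, ood_mode = "shifted_cluster",
    n_test_per_class = 10L, n_ood = 100L, ood_composition = NULL,
    # synthetic images
    image_counts = NULL, image_size = c(32L, 32L), noise_sd = 8,
    # dedup
    hash_algorithm = "dhash", max_hamming = 5L,
    # split / balance
    outer_ratio = 0.8, inner_ratio = 0.8, balance_target = NULL,
    balance_first = FALSE,
    # open-set model
    beta = NULL, tail_size = 20L, threshold = 0.1,
    decision_mode = "score_threshold", mav_source = "all_samples",
    location_mode = "zero",
    # evaluation
    sweep_thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
    # external inputs (override the synth stage)
    activations_path = NULL, test_activations_path = NULL,
    manifest_path = NULL)
}

#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Unknown keys are
#' rejected outright so typos cannot silently fall back to defaults. Call
#' with no arguments (or see `pipeline_defaults` via `pipeline_config()`) for
#' the default values.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7, n_classes = 3, per_class_n = 25)
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("all configuration values must be named")
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(sQuote(bad), collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  if (!cfg$format %in% c("tsv", "csv")) abort("`format` must be tsv or csv")
  structure(cfg, class = "pipeline_config")
}

plog <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    level, sprintf(fmt, ...)))
  }
}

# atomic write: run `writer(tmp)` then rename into place
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("cannot move artifact into '%s'", path))
  path
}

#' Run the open-set workflow
#'
#' Executes an ordered subset of the pipeline stages:
#' \describe{
#'   \item{synth}{generate training / known-test / OOD activation tables and
#'     (when `image_counts` is set) a toy image corpus with manifest.}
#'   \item{dedup}{perceptual-hash the corpus and write the duplicate-group
#'     report.}
#'   \item{split}{stratified train/validation/test assignment of the
#'     manifest.}
#'   \item{balance}{plan and execute class-balancing augmentation (on the
#'     whole corpus when `balance_first`, otherwise intended for the training
#'     partition).}
#'   \item{fit}{fit the open-set model on the training activations and
#'     serialize it.}
#'   \item{predict}{score the evaluation activations (known test + OOD).}
#'   \item{evaluate}{confusion matrix and metric report (JSON + per-class
#'     TSV).}
#'   \item{sweep}{threshold sweep table.}
#' }
#' Stage inputs come from the in-memory state of earlier stages or, when a
#' stage runs standalone, from the files a previous run left in `out_dir`
#' (or the `*_path` configuration keys). Missing inputs abort with the file
#' name. Reruns with an identical configuration and seed write byte-identical
#' activation, model and prediction artifacts.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector, ordered subset of the stage names above.
#' @return Invisibly, a list with the in-memory artifacts (`activations`,
#'   `model`, `predictions`, `report`, `sweep`, ...) and `manifest`, the run
#'   manifest also written to `out_dir/run_manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("synth", "fit", "predict", "evaluate")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("synth", "dedup", "split", "balance", "fit", "predict",
                  "evaluate", "sweep")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(sQuote(bad), collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  artifacts <- character(0)
  add_artifact <- function(path) artifacts <<- c(artifacts, path)
  fmt <- config$format
  ext <- fmt
  opath <- function(name) file.path(config$out_dir, name)

  need_file <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("missing input for stage: %s ('%s' not found)", what,
                    path %||% "<unset>"))
    }
    path
  }

  cfg_model <- function() {
    openmax_config(beta = config$beta, tail_size = config$tail_size,
                   threshold = config$threshold,
                   decision_mode = config$decision_mode,
                   mav_source = config$mav_source,
                   location_mode = config$location_mode)
  }

  for (stage in stages) {
    sseed <- derive_seed(config$seed, stage)
    plog(config, "info", "stage '%s' starting (derived seed %d)", stage, sseed)
    switch(stage,
      synth = {
        spec <- synth_spec(
          n_classes = config$n_classes,
          dim = config$dim %||% config$n_classes,
          per_class_n = config$per_class_n, separation = config$separation,
          spread = config$spread, ood_mode = config$ood_mode, seed = sseed)
        state$train <- synth_activations(spec)
        test_spec <- spec
        test_spec$per_class_n <- as.integer(config$n_test_per_class)
        test_spec$seed <- derive_seed(sseed, "test")
        state$test_known <- synth_activations(test_spec)
        state$test_ood <- synth_ood_activations(
          spec, config$n_ood, composition = config$ood_composition)
        state$test <- dplyr::bind_rows(
          state$test_known, dplyr::select(state$test_ood, -"source"))
        add_artifact(write_atomic(opath(paste0("train_activations.", ext)),
          function(p) write_activations(state$train, p, fmt)))
        add_artifact(write_atomic(opath(paste0("test_activations.", ext)),
          function(p) write_activations(state$test, p, fmt)))
        if (!is.null(config$image_counts)) {
          state$corpus <- synth_image_corpus(
            config$image_counts, config$image_size, config$noise_sd,
            seed = derive_seed(sseed, "images"))
          add_artifact(write_atomic(opath("image_manifest.tsv"),
            function(p) write_tsv_artifact(state$corpus$manifest, p)))
        }
      },
      dedup = {
        if (is.null(state$corpus)) {
          abort("missing input for stage: dedup (no image corpus; run 'synth' with image_counts)")
        }
        hashes <- phash_corpus(state$corpus, config$hash_algorithm)
        state$duplicates <- find_duplicates(hashes, config$max_hamming)
        add_artifact(write_atomic(opath("dedup_report.tsv"),
          function(p) write_tsv_artifact(state$duplicates, p)))
      },
      split = {
        manifest <- state$corpus$manifest %||% {
          p <- need_file(config$manifest_path %||% opath("image_manifest.tsv"),
                         "split")
          readr::read_tsv(p, show_col_types = FALSE)
        }
        state$split <- stratified_split(manifest, config$outer_ratio,
                                        config$inner_ratio, seed = sseed)
        add_artifact(write_atomic(opath("split_assignment.tsv"),
          function(p) write_tsv_artifact(
            dplyr::select(state$split, "image_id", "partition"), p)))
      },
      balance = {
        if (is.null(state$corpus)) {
          abort("missing input for stage: balance (no image corpus in state)")
        }
        manifest <- state$corpus$manifest
        if (!config$balance_first && !is.null(state$split)) {
          train_ids <- state$split$image_id[state$split$partition == "train"]
          manifest <- manifest[manifest$image_id %in% train_ids, , drop = FALSE]
        }
        counts <- table(manifest$label)
        target <- config$balance_target %||% max(counts)
        state$plan <- plan_balance(setNames(as.integer(counts), names(counts)),
                                   target)
        add_artifact(write_atomic(opath("balance_plan.json"),
          function(p) write_balance_plan(state$plan, p)))
        params <- augmentation_params(seed = sseed)
        sub <- state$corpus
        sub$manifest <- manifest
        balanced <- balance_corpus(sub, state$plan, params)
        state$corpus$images <- c(state$corpus$images,
          balanced$images[setdiff(names(balanced$images),
                                  names(state$corpus$images))])
        state$corpus$manifest <- dplyr::bind_rows(
          state$corpus$manifest,
          dplyr::anti_join(balanced$manifest, state$corpus$manifest,
                           by = "image_id"))
        add_artifact(write_atomic(opath("balanced_manifest.tsv"),
          function(p) write_tsv_artifact(state$corpus$manifest, p)))
      },
      fit = {
        train <- state$train %||% {
          p <- need_file(config$activations_path %||%
                           opath(paste0("train_activations.", ext)), "fit")
          read_activations(p, fmt)
        }
        state$model <- fit_open_set_model(train, config = cfg_model())
        add_artifact(write_atomic(opath("model.json"),
          function(p) write_open_set_model(state$model, p)))
      },
      predict = {
        if (is.null(state$model)) {
          p <- need_file(opath("model.json"), "predict")
          state$model <- read_open_set_model(p)
        }
        test <- state$test %||% {
          p <- need_file(config$test_activations_path %||%
                           opath(paste0("test_activations.", ext)), "predict")
          read_activations(p, fmt)
        }
        state$test <- test
        state$predictions <- predict(state$model, test)
        add_artifact(write_atomic(opath(paste0("predictions.", ext)),
          function(p) write_predictions(state$predictions, p, fmt)))
      },
      evaluate = {
        if (is.null(state$predictions) || is.null(state$test)) {
          abort("missing input for stage: evaluate (run 'predict' first)")
        }
        state$report <- evaluation_report(state$test$label, state$predictions,
                                          vocabulary = state$model$vocabulary)
        add_artifact(write_atomic(opath("report.json"), function(p) {
          g <- glance(state$report)
          jsonlite::write_json(as.list(g), p, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
        }))
        add_artifact(write_atomic(opath("report_per_class.tsv"),
          function(p) write_tsv_artifact(tidy(state$report), p)))
      },
      sweep = {
        if (is.null(state$model) && file.exists(opath("model.json"))) {
          state$model <- read_open_set_model(opath("model.json"))
        }
        if (is.null(state$test)) {
          p <- need_file(config$test_activations_path %||%
                           opath(paste0("test_activations.", ext)), "sweep")
          state$test <- read_activations(p, fmt)
        }
        if (is.null(state$model)) abort("missing input for stage: sweep (no model)")
        state$sweep <- threshold_sweep(state$test$label, state$test,
                                       state$model, config$sweep_thresholds)
        add_artifact(write_atomic(opath("threshold_sweep.tsv"),
          function(p) write_tsv_artifact(state$sweep, p)))
      })
    plog(config, "info", "stage '%s' done", stage)
  }

  cfg_serial <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 null = "null", digits = NA)
  manifest <- list(
    config_hash = fnv1a32(utf8ToInt(as.character(cfg_serial))),
    seed = config$seed,
    stages = stages,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("openmosq")),
    artifacts = lapply(setNames(artifacts, basename(artifacts)), fnv1a32_file))
  write_atomic(opath("run_manifest.json"), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  out <- as.list(state)
  out$manifest <- manifest
  invisible(out)
}
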