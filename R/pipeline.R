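# End-to-end orchestration: simulate (or load) -> segment -> extract ->
# cross-validate -> report, with every intermediate artifact written to an
# output directory and full determinism under fixed seeds.

#' Pipeline configuration
#'
#' Bundles the parameters of every stage. Serialises losslessly to and from
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param data simulation settings: `n_sequences`, named `class_mix`
#'   proportions, `seed`, plus any [scenario_spec()] field overrides as
#'   `template`. Ignored when `io$frames_dirs` is set.
#' @param segmentation a [segmentation_params()] or list of its arguments.
#' @param window a [window_config()] or list of its arguments.
#' @param classifier list: `base` ("tree"/"stump"), `rounds`, `max_depth`,
#'   `min_leaf`.
#' @param evaluation list: `folds`, `seed`.
#' @param io list: `out_dir` (artifact directory, optional), `frames_dirs`
#'   (optional character vector of labelled frame directories to use instead
#'   of simulation), `layout` for [load_frame_dataset()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = list(n_sequences = 24L,
                                        class_mix = c(fall = 0.5, walk = 0.5),
                                        seed = 1L),
                            segmentation = segmentation_params(),
                            window = window_config(),
                            classifier = list(base = "tree", rounds = 10L,
                                              max_depth = Inf, min_leaf = 1L),
                            evaluation = list(folds = 10L, seed = 1L),
                            io = list(out_dir = NULL, frames_dirs = NULL,
                                      layout = "frames")) {
  if (!inherits(segmentation, "segmentation_params"))
    segmentation <- do.call(segmentation_params, segmentation)
  if (!inherits(window, "window_config"))
    window <- do.call(window_config, window)
  structure(list(data = data, segmentation = segmentation, window = window,
                 classifier = classifier, evaluation = evaluation, io = io),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$segmentation <- unclass(plain$segmentation)
  plain$window <- unclass(plain$window)
  # named atomic vectors lose their names through YAML; store as a map
  if (!is.null(plain$data$class_mix))
    plain$data$class_mix <- as.list(plain$data$class_mix)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path file written by [write_pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$data$class_mix))
    raw$data$class_mix <- unlist(raw$data$class_mix)
  pipeline_config(
    data = raw$data,
    segmentation = raw$segmentation,
    window = raw$window,
    classifier = raw$classifier,
    evaluation = raw$evaluation,
    io = raw$io %||% list(out_dir = NULL, frames_dirs = NULL,
                          layout = "frames"))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (grepl("^\\[stage:", conditionMessage(e))) stop(e)
    stop_stage(stage, conditionMessage(e))
  })
}

# Features + labels for one (sequence, labels) pair.
sequence_features <- function(sequence, labels, config, seq_id) {
  desc <- pipeline_stage("segment/descriptors",
    compute_descriptors(sequence, config$segmentation))
  fv <- pipeline_stage("features",
    build_feature_vectors(desc, config$window))
  fv$label <- labels[fv$frame_index]
  fv$sequence <- seq_id
  fv
}

#' Run the full fall-detection pipeline
#'
#' Simulates a labelled dataset (or loads frame directories), segments every
#' frame, extracts windowed variance features, and evaluates the boosted
#' classifier by stratified cross-validation. When `config$io$out_dir` is
#' set, intermediate artifacts are written there: `features.csv`,
#' `model.json` (final model trained on all data), `report.json`,
#' `folds.csv`, `roc.csv` (2-class) and `run_metadata.json`.
#'
#' Any stage failure aborts with the stage name in the error message.
#'
#' @param config a [pipeline_config()].
#' @return the `cv_report`, with the feature table attached as attribute
#'   `"features"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$io$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$io$frames_dirs)) {
    sets <- pipeline_stage("load",
      lapply(config$io$frames_dirs, load_frame_dataset,
             layout = config$io$layout %||% "frames"))
    feats <- lapply(seq_along(sets), function(i)
      sequence_features(sets[[i]]$sequence, sets[[i]]$labels, config, i))
  } else {
    tmpl_args <- config$data$template %||% list()
    dataset <- pipeline_stage("simulate", {
      tmpl <- do.call(scenario_spec, tmpl_args)
      generate_dataset(config$data$n_sequences %||% 24L,
                       config$data$class_mix %||% c(fall = 0.5, walk = 0.5),
                       spec_template = tmpl,
                       seed = config$data$seed %||% 1L,
                       keep_masks = FALSE)
    })
    feats <- lapply(seq_along(dataset), function(i)
      sequence_features(dataset[[i]]$sequence, dataset[[i]]$truth$labels,
                        config, i))
  }

  features <- do.call(rbind, feats)
  feat_cols <- setdiff(names(features), c("label", "sequence", "frame_index"))
  X <- as.matrix(features[feat_cols])
  y <- features$label

  report <- pipeline_stage("evaluate",
    kfold_cv(X, y,
             folds = config$evaluation$folds %||% 10L,
             trainer = config$classifier,
             seed = config$evaluation$seed %||% 1L))

  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    final <- pipeline_stage("train",
      train_boosted(X, y,
                    K = config$classifier$rounds %||% 10L,
                    base = config$classifier$base %||% "tree",
                    max_depth = config$classifier$max_depth %||% Inf,
                    min_leaf = config$classifier$min_leaf %||% 1L))
    write_model(final, file.path(out_dir, "model.json"),
                metadata = list(k = config$window$k,
                                feature_names = feat_cols))
    jsonlite::write_json(
      list(accuracy = report$accuracy,
           sensitivity = report$sensitivity,
           specificity = report$specificity,
           auc = report$auc,
           fold_accuracy = report$fold_accuracy,
           confusion = as.data.frame(report$confusion$table),
           n_windows = nrow(features)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    utils::write.csv(
      data.frame(sample = seq_along(report$fold_id), fold = report$fold_id,
                 label = y, prediction = report$predictions),
      file.path(out_dir, "folds.csv"), row.names = FALSE)
    if (!is.null(report$roc))
      utils::write.csv(report$roc, file.path(out_dir, "roc.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(package = "fallvar",
           version = as.character(utils::packageVersion("fallvar")),
           data_seed = config$data$seed %||% 1L,
           eval_seed = config$evaluation$seed %||% 1L,
           n_sequences = config$data$n_sequences,
           n_windows = nrow(features),
           windows_per_class = as.list(table(y))),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }

  attr(report, "features") <- features
  report
}
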