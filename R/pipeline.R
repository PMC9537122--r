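#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end experiment.  All randomness is
#' derived from the single `seed`, so a run is fully reproducible from
#' its resolved configuration.
#'
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param cohort a [cohort_config()]; by default the standard 32 + 32
#'   synthetic cohort seeded from `seed`.
#' @param window_s segment window in seconds.
#' @param rules a [quality_rules()] object.
#' @param preprocess a [preprocess_params()] object.
#' @param selection_threshold point-biserial selection threshold.
#' @param feature_mode `"t_filtered"` (selected markers that also pass
#'   the Welch test, the default) or `"selected"` (all markers above the
#'   correlation threshold).
#' @param folds cross-validation folds.
#' @param opt_iterations hyperparameter-search budget for the KNN.
#' @param opt_method `"gp"` or `"random"` (see [optimize_hyperparams()]).
#' @param comparison_presets names from [classifier_presets()] evaluated
#'   alongside the optimized KNN.
#' @return an object of class `ppg_run_config`.
#' @export
run_config <- function(seed = 1L, cohort = default_cohort_config(seed),
                       window_s = 5, rules = quality_rules(),
                       preprocess = preprocess_params(),
                       selection_threshold = 0.6,
                       feature_mode = c("t_filtered", "selected"),
                       folds = 10, opt_iterations = 30,
                       opt_method = c("gp", "random"),
                       comparison_presets = c("discriminant",
                                              "svm_linear")) {
  feature_mode <- match.arg(feature_mode)
  opt_method <- match.arg(opt_method)
  structure(
    list(seed = as.integer(seed), cohort = cohort, window_s = window_s,
         rules = rules, preprocess = preprocess,
         selection_threshold = selection_threshold,
         feature_mode = feature_mode, folds = folds,
         opt_iterations = opt_iterations, opt_method = opt_method,
         comparison_presets = comparison_presets),
    class = "ppg_run_config"
  )
}

#' Run the full experiment
#'
#' Generates (or takes) a cohort, extracts the per-segment feature table,
#' selects markers, splits subjects into halves, tunes the KNN by
#' sequential model-based search on the training half, trains the tuned
#' KNN and the comparison presets, and evaluates everything on the
#' held-out subject half.  When `out_dir` is given, the feature table,
#' selection report, serialized models, evaluation report, and resolved
#' configuration are written there.
#'
#' @param config a [run_config()].
#' @param records optional pre-made cohort (list of `ppg_record`);
#'   generated from `config$cohort` when `NULL`.
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return an object of class `ppg_run` with components `features`,
#'   `selection`, `split`, `tuning`, `models`, `evaluations`.
#' @export
run_pipeline <- function(config = run_config(), records = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ppg_run_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("stage: cohort")
  if (is.null(records)) {
    records <- stage("cohort", generate_cohort(config$cohort))
  }
  say("stage: features")
  features <- stage("features", extract_features(
    records, window_s = config$window_s, rules = config$rules,
    params = config$preprocess))
  if (nrow(features) == 0) stop("pipeline stage 'features' produced no segments")
  say("stage: selection")
  selection <- stage("selection", select_features(
    features, threshold = config$selection_threshold))
  feats <- if (config$feature_mode == "t_filtered") {
    selection$classifier_features
  } else selection$selected
  if (length(feats) == 0) {
    stop("pipeline stage 'classify' aborted: feature selection is empty ",
         "(no marker exceeded |r| > ", config$selection_threshold, ")")
  }
  say("stage: split")
  split <- stage("split", subject_half_split(features, seed = config$seed))
  train_tab <- features[features$subject_id %in% split$train, ]
  test_tab <- features[features$subject_id %in% split$test, ]
  say("stage: tune KNN (", config$opt_iterations, " iterations)")
  tuning <- stage("tune", optimize_hyperparams(
    train_tab, feats, family = "knn", iterations = config$opt_iterations,
    folds = config$folds, seed = config$seed, method = config$opt_method))
  say("stage: train + evaluate")
  to_fit <- c(list(knn = list(family = "knn", params = tuning$best_params)),
              classifier_presets()[config$comparison_presets])
  X_train <- as.matrix(train_tab[, feats, drop = FALSE])
  y_train <- as_anes_label(train_tab$label)
  models <- lapply(to_fit, function(spec)
    stage("train", fit_classifier(spec$family, spec$params,
                                  X_train, y_train)))
  evaluations <- lapply(models, function(m)
    stage("evaluate", evaluate_classifier(m, test_tab, feats)))
  run <- structure(
    list(features = features, selection = selection, split = split,
         tuning = tuning, models = models, evaluations = evaluations,
         classifier_features = feats, config = config),
    class = "ppg_run"
  )
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

#' @export
print.ppg_run <- function(x, ...) {
  cat("<ppg_run>", nrow(x$features), "segments,",
      length(unique(x$features$subject_id)), "subjects\n")
  cat("selected markers:", paste(x$selection$selected, collapse = ", "),
      "\n")
  cat("classifier features:", paste(x$classifier_features,
                                    collapse = ", "), "\n")
  cat("tuned KNN:", paste(names(x$tuning$best_params),
                          unlist(x$tuning$best_params),
                          sep = "=", collapse = " "),
      sprintf("(CV error %.3f)\n", x$tuning$best_error))
  for (nm in names(x$evaluations)) {
    ev <- x$evaluations[[nm]]
    cat(sprintf("  %-14s accuracy=%.3f AUC=%.3f kappa=%.3f\n",
                nm, ev$accuracy, ev$auc, ev$cohen_kappa))
  }
  invisible(x)
}

# Write run outputs: feature CSV, selection + evaluation JSON, models,
# and the resolved configuration as YAML.
.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(scores = run$selection$scores,
         threshold = run$selection$threshold,
         selected = run$selection$selected,
         classifier_features = run$classifier_features),
    file.path(out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (nm in names(run$models)) {
    model_to_json(run$models[[nm]],
                  file.path(out_dir, "models", paste0(nm, ".json")))
  }
  evals <- lapply(run$evaluations, function(ev) {
    ev$predictions <- NULL
    ev$roc <- NULL
    unclass(ev)
  })
  jsonlite::write_json(
    list(split = list(train = run$split$train, test = run$split$test),
         tuned_knn = run$tuning$best_params,
         cv_error = run$tuning$best_error,
         evaluations = evals),
    file.path(out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA)
  write.csv(run$tuning$trace, file.path(out_dir, "tuning_trace.csv"),
            row.names = FALSE)
  yaml::write_yaml(resolve_config(run$config),
                   file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

#' Flatten a run configuration into plain YAML-serializable values
#'
#' @param config a [run_config()].
#' @return nested list of numbers and strings.
#' @export
resolve_config <- function(config) {
  flatten <- function(x) {
    if (inherits(x, "ppg_pulse_shape") || inherits(x, "ppg_noise_params") ||
        inherits(x, "ppg_quality_rules") ||
        inherits(x, "ppg_preprocess_params")) {
      return(lapply(unclass(x), flatten))
    }
    if (inherits(x, "ppg_shape_mixture")) {
      return(list(shapes = lapply(x$shapes, flatten),
                  weights = x$weights, names = x$names))
    }
    if (inherits(x, "ppg_cohort_config")) {
      return(lapply(unclass(x), flatten))
    }
    if (is.function(x)) return(NULL)
    x
  }
  lapply(unclass(config), flatten)
}
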