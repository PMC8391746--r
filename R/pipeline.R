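# End-to-end convenience: build the documented synthetic benchmark, fit and
# calibrate a model, and evaluate it. This is the harness the package's own
# tests and the reproduction script drive.

#' Default benchmark configuration
#'
#' The documented synthetic benchmark: window counts per split, forest
#' parameters (2000 trees, 5% anomaly proportion metadata, subsample 256)
#' and the grade mixtures of [make_dataset()].
#'
#' @param kind `"ECG"` or `"RESP"`.
#' @return a named list of benchmark parameters.
#' @export
benchmark_config <- function(kind = c("ECG", "RESP")) {
  kind <- match.arg(kind)
  list(kind = kind,
       n_train = if (kind == "ECG") 800 else 500,
       n_validation = 1200,
       n_test = if (kind == "ECG") 800 else 600,
       n_trees = 2000, psi = 256, contamination = 0.05)
}

#' Run the full SQA benchmark for one signal kind
#'
#' Generates the synthetic dataset, extracts features, fits the isolation
#' forest on the unlabeled training features, calibrates the two grade
#' thresholds on the labeled validation scores, and evaluates on validation
#' and test sets.
#'
#' @param kind `"ECG"` or `"RESP"`.
#' @param seed master seed; the dataset, forest and subsampling seeds are
#'   derived from it.
#' @param config overrides for [benchmark_config()] entries.
#' @return list with the dataset splits' features and labels, the calibrated
#'   `model`, `thresholds`, and `sqa_report`s for validation and test.
#' @export
run_benchmark <- function(kind = c("ECG", "RESP"), seed = 1L, config = list()) {
  kind <- match.arg(kind)
  cfg <- utils::modifyList(benchmark_config(kind), config)
  ds <- make_dataset(kind, n_train = cfg$n_train,
                     n_validation = cfg$n_validation, n_test = cfg$n_test,
                     seed = seed)
  train_f <- extract_features(ds$train)
  val_f <- extract_features(ds$validation$records)
  test_f <- extract_features(ds$test$records)
  val_f$grade <- ds$validation$labels$grade[
    match(val_f$record_id, ds$validation$labels$record_id)]
  test_f$grade <- ds$test$labels$grade[
    match(test_f$record_id, ds$test$labels$record_id)]

  model <- iforest_fit(feature_matrix(train_f, kind),
                       n_trees = cfg$n_trees, psi = cfg$psi,
                       contamination = cfg$contamination, seed = seed + 1L)
  val_scores <- anomaly_score(model, feature_matrix(val_f, kind))
  test_scores <- anomaly_score(model, feature_matrix(test_f, kind))
  thr <- find_thresholds(val_scores, val_f$grade)
  model$calibration <- thr
  val_pred <- classify(val_scores, thr, val_f$flatline)
  test_pred <- classify(test_scores, thr, test_f$flatline)
  list(kind = kind, config = cfg, seed = seed,
       train_features = train_f, validation_features = val_f,
       test_features = test_f,
       val_scores = val_scores, test_scores = test_scores,
       model = model, thresholds = thr,
       val_report = score_report(val_f$grade, val_pred),
       test_report = score_report(test_f$grade, test_pred))
}
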