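# File formats: CSV records (time_s,value), label CSV, feature CSV, portable
# JSON model files (splits, sizes, params, calibration), track CSV and
# report JSON. Times are seconds from record start; intervals are half-open.

#' Write / read a signal record as CSV
#'
#' Two columns `time_s,value`; the sampling rate is recovered from the time
#' column on read (it must be uniform).
#'
#' @param record a `signal_record`.
#' @param path output path.
#' @return `path`, invisibly (writer); a `signal_record` (reader).
#' @export
write_record_csv <- function(record, path) {
  t <- record$t0 + (seq_along(record$samples) - 1) / record$fs
  df <- data.frame(time_s = sprintf("%.6f", t),
                   value = sprintf("%.17g", record$samples))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @param kind,record_id metadata for the reader (CSV carries none).
#' @export
read_record_csv <- function(path, kind = c("ECG", "RESP"), record_id = NULL) {
  kind <- match.arg(kind)
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop_param("%s: expected columns time_s,value", path)
  }
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-6)) stop_param("%s: non-uniform sampling", path)
  if (is.null(record_id)) record_id <- sub("\\.csv$", "", basename(path))
  signal_record(df$value, fs = 1 / dt[1], kind = kind, t0 = df$time_s[1],
                record_id = record_id)
}

#' Write / read a window label file
#'
#' CSV with columns `record_id, window_start_s, window_len_s, grade`.
#'
#' @param labels data frame in that layout.
#' @param path file path.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(all(c("record_id", "window_start_s", "window_len_s", "grade")
                %in% names(labels)))
  write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(df$grade %in% GRADES)) stop_param("%s: unknown grade values", path)
  df
}

#' Write / read a feature matrix CSV
#'
#' One row per window keyed by `(record_id, start_s)`, header = feature
#' names.
#'
#' @param features data frame from [extract_features()].
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted model (with optional calibration) to portable JSON
#'
#' The JSON carries the schema version, forest parameters, per-tree node
#' tables and, when present, the calibrated thresholds, so scoring is
#' reproducible across platforms.
#'
#' @param model an `iforest_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "iforest_model"))
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              n_trees = model$n_trees, psi = model$psi,
              contamination = model$contamination, seed = model$seed,
              cpsi = model$cpsi, feature_names = model$feature_names,
              trees = lapply(model$trees, function(m) unname(as.matrix(m))))
  if (!is.null(model$calibration)) {
    cal <- model$calibration
    obj$calibration <- list(T1 = cal$T1, T2 = cal$T2,
                            n_labels = cal$n_labels, accuracy = cal$accuracy,
                            macro_f1 = cal$macro_f1)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    stop_param("%s: unsupported model schema %s", path, obj$schema_version)
  }
  cn <- c("feature", "split", "left", "right", "size", "cterm")
  trees <- lapply(obj$trees, function(m) {
    m <- matrix(as.numeric(m), ncol = 6)
    colnames(m) <- cn
    m
  })
  model <- structure(list(trees = trees, n_trees = obj$n_trees,
                          psi = obj$psi, contamination = obj$contamination,
                          feature_names = obj$feature_names, seed = obj$seed,
                          cpsi = obj$cpsi),
                     class = "iforest_model")
  if (!is.null(obj$calibration)) {
    model$calibration <- quality_thresholds(
      obj$calibration$T1, obj$calibration$T2, obj$calibration$n_labels,
      obj$calibration$accuracy, obj$calibration$macro_f1)
  }
  model
}

#' Write a quality track as CSV
#'
#' Columns `start_s, end_s, grade`; times formatted at 3 decimals.
#'
#' @param track a `quality_track`.
#' @param path file path.
#' @export
write_track_csv <- function(track, path) {
  df <- data.frame(start_s = sprintf("%.3f", track$start_s),
                   end_s = sprintf("%.3f", track$end_s), grade = track$grade)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report an `sqa_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(n = report$n, accuracy = report$accuracy,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall, macro_f1 = report$macro_f1,
              confusion = unname(report$confusion),
              per_class = as.data.frame(report$per_class))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
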