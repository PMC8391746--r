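# Quantitative evaluation: confusion matrices and accuracy / macro metrics,
# the label-efficiency protocol, and the color-coded per-record quality
# track.

#' Classification report for three-grade predictions
#'
#' 3x3 confusion matrix (rows = true, columns = predicted), overall accuracy,
#' per-class precision/recall/F1 and their unweighted (macro) means.
#' Zero-denominator classes contribute 0 to the macro means.
#'
#' @param true_labels,pred_labels equal-length grade vectors.
#' @return an `sqa_report` list.
#' @export
score_report <- function(true_labels, pred_labels) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels) || length(true_labels) < 1) {
    stop_param("label vectors must be equal-length and non-empty")
  }
  if (!all(c(true_labels, pred_labels) %in% GRADES)) {
    stop_param("unknown grade label")
  }
  n <- length(true_labels)
  cm <- table(factor(true_labels, GRADES), factor(pred_labels, GRADES))
  cm <- matrix(as.numeric(cm), 3, 3, dimnames = list(true = GRADES, pred = GRADES))
  per <- lapply(seq_along(GRADES), function(k) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  rownames(per) <- GRADES
  structure(list(confusion = cm, accuracy = sum(diag(cm)) / n,
                 per_class = per,
                 macro_precision = mean(per[, "precision"]),
                 macro_recall = mean(per[, "recall"]),
                 macro_f1 = mean(per[, "f1"]), n = n),
            class = "sqa_report")
}

#' @export
print.sqa_report <- function(x, ...) {
  cat(sprintf("SQA report (n = %d)\naccuracy: %.4f  macro-P/R/F1: %.4f / %.4f / %.4f\n",
              x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Label-efficiency experiment
#'
#' For each label budget `n`: draw `n` validation labels uniformly without
#' replacement, calibrate thresholds on them, classify the full test set and
#' record the accuracy; repeat, and report mean and SD of accuracy per
#' budget.
#'
#' @param val_scores,val_labels anomaly scores and grades of the labeled
#'   validation windows.
#' @param test_scores,test_labels the full test set.
#' @param ns label budgets (default `c(200, 600, 1000)`).
#' @param repeats repeats per budget (default 30).
#' @param seed master seed for the subsampling.
#' @param test_flatline logical flatline flags for the test windows.
#' @return data frame `n`, `mean_accuracy`, `sd_accuracy`, `repeats`.
#' @export
label_efficiency_experiment <- function(val_scores, val_labels,
                                        test_scores, test_labels,
                                        ns = c(200, 600, 1000), repeats = 30,
                                        seed = 1L, test_flatline = FALSE) {
  if (max(ns) > length(val_labels)) {
    stop_param("largest budget %d exceeds the %d available labels",
               max(ns), length(val_labels))
  }
  res <- lapply(ns, function(n) {
    acc <- vapply(seq_len(repeats), function(r) {
      idx <- subsample_labels(length(val_labels), n, r, seed)
      thr <- suppressWarnings(find_thresholds(val_scores[idx], val_labels[idx]))
      mean(classify(test_scores, thr, test_flatline) == test_labels)
    }, 0)
    data.frame(n = n, mean_accuracy = mean(acc),
               sd_accuracy = if (repeats > 1) sd(acc) else 0,
               repeats = repeats)
  })
  do.call(rbind, res)
}

#' Build a color-coded quality track for a record
#'
#' Windows the record, conditions and scores each window, classifies it with
#' the calibrated thresholds, and merges adjacent equal-grade intervals. The
#' track tiles the windowed span exactly with half-open `[start, end)`
#' intervals.
#'
#' @param record a `signal_record`.
#' @param model a fitted `iforest_model` for the record's kind.
#' @param thresholds a `quality_thresholds`; defaults to `model$calibration`.
#' @param stride_s window stride (default window length).
#' @return a `quality_track` data frame `start_s`, `end_s`, `grade`.
#' @export
build_quality_track <- function(record, model, thresholds = NULL,
                                stride_s = NULL) {
  if (is.null(thresholds)) thresholds <- model$calibration
  if (is.null(thresholds)) stop_param("model has no calibration; pass thresholds")
  feats <- extract_features(list(record), stride_s)
  if (is.null(feats) || nrow(feats) == 0) {
    warning("record shorter than one window; empty track")
    return(structure(data.frame(start_s = numeric(0), end_s = numeric(0),
                                grade = character(0)),
                     class = c("quality_track", "data.frame")))
  }
  sc <- anomaly_score(model, feature_matrix(feats, record$kind))
  grade <- classify(sc, thresholds, feats$flatline)
  len <- window_length_s(record$kind)
  df <- data.frame(start_s = feats$start_s, end_s = feats$start_s + len,
                   grade = grade, stringsAsFactors = FALSE)
  merge_track(df)
}

merge_track <- function(df) {
  if (nrow(df) > 1) {
    keep <- c(TRUE, df$grade[-1] != df$grade[-nrow(df)])
    grp <- cumsum(keep)
    df <- data.frame(start_s = tapply(df$start_s, grp, min),
                     end_s = tapply(df$end_s, grp, max),
                     grade = df$grade[keep], stringsAsFactors = FALSE,
                     row.names = NULL)
  }
  structure(df, class = c("quality_track", "data.frame"))
}

#' Plot a quality track as a color strip
#'
#' Green = good, yellow = acceptable, red = unacceptable.
#'
#' @param x a `quality_track`.
#' @param ... passed to `plot`.
#' @export
plot.quality_track <- function(x, ...) {
  cols <- c(good = "forestgreen", acceptable = "gold", unacceptable = "firebrick")
  graphics::plot(NULL, xlim = range(c(x$start_s, x$end_s)), ylim = c(0, 1),
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  graphics::rect(x$start_s, 0.2, x$end_s, 0.8, col = cols[x$grade], border = NA)
  invisible(x)
}
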