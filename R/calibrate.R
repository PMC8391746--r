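# Semisupervised calibration: an exhaustive two-threshold search on a small
# labeled set maps the anomaly-score axis to the three quality grades.

#' Quality thresholds constructor
#'
#' An ordered pair `(T1, T2)` on the anomaly-score axis: scores below `T1`
#' are good, in `[T1, T2)` acceptable, at or above `T2` unacceptable.
#'
#' @param T1,T2 thresholds with `T1 <= T2`.
#' @param n_labels,accuracy,macro_f1 fitting metadata.
#' @return a `quality_thresholds` object.
#' @export
quality_thresholds <- function(T1, T2, n_labels = NA_integer_,
                               accuracy = NA_real_, macro_f1 = NA_real_) {
  if (!is.finite(T1) || !is.finite(T2) || T1 > T2) {
    stop_param("need finite T1 <= T2, got (%g, %g)", T1, T2)
  }
  structure(list(T1 = T1, T2 = T2, n_labels = n_labels,
                 accuracy = accuracy, macro_f1 = macro_f1),
            class = "quality_thresholds")
}

#' @export
print.quality_thresholds <- function(x, ...) {
  cat(sprintf("<quality_thresholds> T1 = %.4f, T2 = %.4f (n = %s, acc = %s)\n",
              x$T1, x$T2, x$n_labels,
              ifelse(is.na(x$accuracy), "NA", sprintf("%.3f", x$accuracy))))
  invisible(x)
}

#' Map anomaly scores to quality grades
#'
#' Half-open convention: `score < T1` is good, `T1 <= score < T2` acceptable,
#' `score >= T2` unacceptable. Flatline-flagged windows are unacceptable
#' regardless of score.
#'
#' @param score numeric vector of anomaly scores.
#' @param thresholds a `quality_thresholds`.
#' @param flatline logical vector (recycled) of flatline flags.
#' @return character vector of grades.
#' @export
classify <- function(score, thresholds, flatline = FALSE) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  g <- ifelse(score < thresholds$T1, "good",
              ifelse(score < thresholds$T2, "acceptable", "unacceptable"))
  g[rep_len(flatline, length(g))] <- "unacceptable"
  g
}

# 3x3 confusion counts from prefix sums at cut positions (i, j): the i
# lowest-scoring windows are predicted good, the next j - i acceptable
macro_f1_at <- function(G, A, U, i, j, n) {
  cm <- rbind(good = c(G[i + 1], G[j + 1] - G[i + 1], G[n + 1] - G[j + 1]),
              acceptable = c(A[i + 1], A[j + 1] - A[i + 1], A[n + 1] - A[j + 1]),
              unacceptable = c(U[i + 1], U[j + 1] - U[i + 1], U[n + 1] - U[j + 1]))
  f1 <- vapply(1:3, function(k) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, 0)
  mean(f1)
}

#' Calibrate the two grade thresholds on labeled scores
#'
#' Exhaustive search over candidate pairs drawn from midpoints of adjacent
#' sorted unique scores (plus the range extremes, slightly extended so the
#' all-one-grade partitions are expressible), maximizing overall accuracy.
#' Ties are broken by highest macro-F1, then smallest `T2 - T1`, then
#' smallest `T1`, so the result is deterministic and order-independent.
#'
#' @param scores finite anomaly scores of the labeled windows.
#' @param labels grades (`"good"`, `"acceptable"`, `"unacceptable"`).
#' @return a `quality_thresholds` with achieved accuracy and macro-F1.
#' @export
find_thresholds <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) < 1) {
    stop_param("scores and labels must be equal-length, non-empty")
  }
  if (any(!is.finite(scores))) stop_param("scores must be finite")
  labels <- as.character(labels)
  if (!all(labels %in% GRADES)) stop_param("unknown grade label")
  eps <- 1e-9 * max(1, diff(range(scores)))
  lo <- min(scores) - eps
  hi <- max(scores) + eps
  if (length(unique(labels)) < 2) {
    warning("all labels are one grade; thresholds set at range extremes")
    thr <- switch(labels[1],
                  good = quality_thresholds(hi, hi),
                  acceptable = quality_thresholds(lo, hi),
                  unacceptable = quality_thresholds(lo, lo))
    thr$n_labels <- length(labels)
    thr$accuracy <- 1
    return(thr)
  }
  o <- order(scores)
  s <- scores[o]
  l <- labels[o]
  u <- unique(s)
  k <- length(u)
  mids <- if (k > 1) (u[-k] + u[-1]) / 2 else numeric(0)
  cand <- c(lo, mids, hi)
  # cut position of each candidate = number of scores strictly below it
  pos <- c(0, cumsum(tabulate(match(s, u), k))[-k], length(s))
  n <- length(s)
  G <- c(0, cumsum(l == "good"))
  A <- c(0, cumsum(l == "acceptable"))
  U <- c(0, cumsum(l == "unacceptable"))
  K <- length(cand)
  # accuracy(i, j) = G[pos_i] + (A[pos_j] - A[pos_i]) + (U[n] - U[pos_j])
  gi <- G[pos + 1] - A[pos + 1]
  aj <- A[pos + 1] - U[pos + 1]
  acc <- outer(gi, rep(1, K)) + outer(rep(1, K), aj) + U[n + 1]
  acc[lower.tri(acc)] <- -Inf   # require i <= j
  best <- max(acc)
  ties <- which(acc >= best - 1e-9, arr.ind = TRUE)
  if (nrow(ties) > 1) {
    f1 <- vapply(seq_len(nrow(ties)), function(r) {
      macro_f1_at(G, A, U, pos[ties[r, 1]], pos[ties[r, 2]], n)
    }, 0)
    ties <- ties[f1 >= max(f1) - 1e-12, , drop = FALSE]
  } else {
    f1 <- macro_f1_at(G, A, U, pos[ties[1, 1]], pos[ties[1, 2]], n)
  }
  span <- cand[ties[, 2]] - cand[ties[, 1]]
  ties <- ties[span <= min(span) + 1e-15, , drop = FALSE]
  pick <- ties[which.min(cand[ties[, 1]]), , drop = FALSE]
  thr <- quality_thresholds(cand[pick[1, 1]], cand[pick[1, 2]],
                            n_labels = n, accuracy = best / n,
                            macro_f1 = macro_f1_at(G, A, U, pos[pick[1, 1]],
                                                   pos[pick[1, 2]], n))
  thr
}

#' Subsample labeled windows for threshold calibration
#'
#' Uniform draw without replacement, deterministic per (n, repeat index,
#' master seed). Used by the label-efficiency protocol.
#'
#' @param n_available number of labeled windows available.
#' @param n subset size (`n <= n_available`).
#' @param rep_index repeat index (1-based).
#' @param seed master seed.
#' @return sorted integer indices of the selected labels; `n = n_available`
#'   returns `1:n` exactly.
#' @export
subsample_labels <- function(n_available, n, rep_index = 1L, seed = 1L) {
  if (n > n_available) {
    stop_param("cannot draw %d labels from %d available", n, n_available)
  }
  if (n == n_available) return(seq_len(n))
  set.seed(((as.integer(seed) %% 1000003L) * 1009L + as.integer(rep_index)) %%
             2147483647L)
  sort(sample.int(n_available, n))
}
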