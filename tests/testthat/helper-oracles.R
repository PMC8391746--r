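# Independent oracles used to validate the package implementations.

# Direct-moment oracle: explicit sums, population convention.
oracle_skewness <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  sum(((x - mu) / sigma)^3) / n
}

oracle_kurtosis <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  sum(((x - mu) / sigma)^4) / n
}

# Exhaustive warping-path enumeration: minimum total |a_i - b_j| cost over
# all monotone paths from (1,1) to (n,m); exponential, for tiny inputs only.
oracle_dtw <- function(a, b) {
  enum <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == length(a) && j == length(b)) return(c0)
    nxt <- Inf
    if (i < length(a)) nxt <- min(nxt, enum(i + 1, j))
    if (j < length(b)) nxt <- min(nxt, enum(i, j + 1))
    if (i < length(a) && j < length(b)) nxt <- min(nxt, enum(i + 1, j + 1))
    c0 + nxt
  }
  enum(1, 1)
}

# Straightforward recursive isolation-tree reference. Consumes the RNG in
# the same documented order as the package (one sample.int over candidate
# features, one runif for the split) so that, replayed under the same seed,
# it must reproduce the package's trees exactly.
ref_grow_tree <- function(X, idx, height, hlim) {
  if (height >= hlim || length(idx) <= 1) {
    return(list(external = TRUE, size = length(idx)))
  }
  rng <- vapply(seq_len(ncol(X)), function(f) range(X[idx, f]), c(0, 0))
  cand <- which(rng[2, ] > rng[1, ])
  if (!length(cand)) return(list(external = TRUE, size = length(idx)))
  f <- cand[sample.int(length(cand), 1)]
  split <- runif(1, rng[1, f], rng[2, f])
  left <- idx[X[idx, f] < split]
  right <- idx[X[idx, f] >= split]
  if (!length(left) || !length(right)) {
    return(list(external = TRUE, size = length(idx)))
  }
  list(external = FALSE, feature = f, split = split, size = length(idx),
       left = ref_grow_tree(X, left, height + 1, hlim),
       right = ref_grow_tree(X, right, height + 1, hlim))
}

ref_path_length <- function(node, x) {
  if (node$external) return(average_path_normalizer_c(node$size))
  1 + if (x[node$feature] < node$split) ref_path_length(node$left, x)
  else ref_path_length(node$right, x)
}

# Walk a package tree matrix and a reference tree in parallel, asserting
# identical structure (features, splits, sizes).
expect_same_tree <- function(tree_mat, ref, row = 1) {
  if (ref$external) {
    expect_equal(unname(tree_mat[row, "feature"]), 0)
    expect_equal(unname(tree_mat[row, "size"]), ref$size)
  } else {
    expect_equal(unname(tree_mat[row, "feature"]), ref$feature)
    expect_equal(unname(tree_mat[row, "split"]), ref$split)
    expect_equal(unname(tree_mat[row, "size"]), ref$size)
    expect_same_tree(tree_mat, ref$left, tree_mat[row, "left"])
    expect_same_tree(tree_mat, ref$right, tree_mat[row, "right"])
  }
}

# Brute-force two-threshold search: every candidate pair, same tie-breaks.
oracle_find_thresholds <- function(scores, labels) {
  eps <- 1e-9 * max(1, diff(range(scores)))
  u <- sort(unique(scores))
  cand <- c(min(scores) - eps,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            max(scores) + eps)
  best <- NULL
  for (t1 in cand) for (t2 in cand) {
    if (t1 > t2) next
    pred <- ifelse(scores < t1, "good",
                   ifelse(scores < t2, "acceptable", "unacceptable"))
    acc <- mean(pred == labels)
    cm <- table(factor(labels, c("good", "acceptable", "unacceptable")),
                factor(pred, c("good", "acceptable", "unacceptable")))
    f1 <- mean(vapply(1:3, function(k) {
      tp <- cm[k, k]
      p <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
      r <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
      if (p + r > 0) 2 * p * r / (p + r) else 0
    }, 0))
    key <- c(acc, f1, -(t2 - t1), -t1)
    if (is.null(best) || lex_gt(key, best$key)) {
      best <- list(T1 = t1, T2 = t2, accuracy = acc, macro_f1 = f1, key = key)
    }
  }
  best
}

lex_gt <- function(a, b, tol = 1e-9) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + tol) return(TRUE)
    if (a[i] < b[i] - tol) return(FALSE)
  }
  FALSE
}

# Naive per-class counting report oracle.
oracle_report <- function(truth, pred) {
  grades <- c("good", "acceptable", "unacceptable")
  cm <- matrix(0, 3, 3, dimnames = list(true = grades, pred = grades))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
  list(confusion = cm, accuracy = sum(diag(cm)) / length(truth))
}

# Build a ground_truth object directly (labeler unit tests).
mk_truth <- function(kind, wander = 0, impulses = 0L, dropout = 0, emg_s = 0,
                     emg_rel = 0, unreadable = 0L, regular = 1, apnea = 0) {
  len <- if (kind == "ECG") 10 else 30
  structure(list(kind = kind, start_s = 0, length_s = len,
                 wander_ratio = wander, n_impulses = impulses,
                 dropout_s = dropout, emg_s = emg_s, emg_rel = emg_rel,
                 n_beats = 10L, unreadable_beats = unreadable,
                 ectopic = FALSE, apnea_s = apnea,
                 regular_fraction = regular),
            class = "ground_truth")
}

grade_rank <- function(g) match(g, c("good", "acceptable", "unacceptable"))

# conditioned window straight from a generator record (first window)
first_window <- function(record) {
  condition_window(segment_windows(record)[[1]])
}
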