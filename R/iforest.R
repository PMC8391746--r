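# From-scratch isolation forest. Trees are grown on uniform subsamples with
# uniformly random split features and split values; the anomaly score
# s = 2^(-E[h]/c(psi)) is the quality axis the calibrated thresholds cut.
#
# Trees are stored as numeric matrices (one row per node) with columns
# feature (0 = external), split, left, right (1-based row indices), size,
# cterm (= c(size) at external nodes), which the C++ scorer traverses.

#' Average unsuccessful-search path length c(n)
#'
#' Expected path length of an unsuccessful search in a binary search tree of
#' `n` points, used to normalize isolation path lengths: `c(0) = c(1) = 0`;
#' for `n >= 2`, `c(n) = 2 H(n-1) - 2 (n-1)/n` with exact harmonic numbers up
#' to n = 1000 and the `ln + gamma` approximation above.
#'
#' @param n non-negative integer (vectorized).
#' @return c(n).
#' @export
average_path_normalizer_c <- function(n) {
  if (any(n < 0)) stop_param("n must be >= 0")
  vapply(n, function(ni) {
    if (ni <= 1) return(0)
    h <- if (ni <= 1000) sum(1 / seq_len(ni - 1))
    else log(ni - 1) + 0.5772156649015329
    2 * h - 2 * (ni - 1) / ni
  }, 0)
}

# Recursive tree growth. RNG draw order per internal node (documented, relied
# on by the reference-equivalence tests): one sample.int() over the valid
# split features, then one runif() in that feature's (min, max) node range.
grow_itree <- function(X, idx, hlim) {
  nodes <- list()
  grow <- function(idx, height) {
    row <- length(nodes) + 1L
    nodes[[row]] <<- c(0, 0, 0, 0, length(idx), 0)  # placeholder
    if (height >= hlim || length(idx) <= 1) {
      nodes[[row]][6] <<- average_path_normalizer_c(length(idx))
      return(row)
    }
    rng <- vapply(seq_len(ncol(X)), function(f) range(X[idx, f]), c(0, 0))
    cand <- which(rng[2, ] > rng[1, ])
    if (!length(cand)) {  # constant node: terminate as external
      nodes[[row]][6] <<- average_path_normalizer_c(length(idx))
      return(row)
    }
    f <- cand[sample.int(length(cand), 1)]
    split <- runif(1, rng[1, f], rng[2, f])
    left <- idx[X[idx, f] < split]
    right <- idx[X[idx, f] >= split]
    if (!length(left) || !length(right)) {
      nodes[[row]][6] <<- average_path_normalizer_c(length(idx))
      return(row)
    }
    li <- grow(left, height + 1)
    ri <- grow(right, height + 1)
    nodes[[row]] <<- c(f, split, li, ri, length(idx), 0)
    row
  }
  grow(idx, 0)
  m <- do.call(rbind, nodes)
  colnames(m) <- c("feature", "split", "left", "right", "size", "cterm")
  m
}

#' Fit an isolation forest
#'
#' Grows `n_trees` isolation trees, each on an independent uniform subsample
#' of `psi` rows without replacement, with split features chosen uniformly at
#' random among non-constant features and split values uniform in the node's
#' feature range; trees stop at height `ceiling(log2(psi))` or single-point
#' nodes. Deterministic given the seed.
#'
#' @param X numeric feature matrix (rows = windows); must be finite.
#' @param n_trees ensemble size (default 2000).
#' @param psi subsample size (default 256; shrunk with a warning if `X` has
#'   fewer rows).
#' @param contamination expected anomaly proportion (default 0.05). Stored as
#'   metadata only: grades come from the calibrated thresholds, never from
#'   this value.
#' @param seed integer seed.
#' @return an `iforest_model`.
#' @export
iforest_fit <- function(X, n_trees = 2000, psi = 256, contamination = 0.05,
                        seed = 1L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop_param("X must be a finite numeric matrix")
  }
  if (n_trees < 1) stop_param("n_trees must be >= 1")
  if (psi < 2) stop_param("psi must be >= 2")
  n <- nrow(X)
  if (n < psi) {
    warning(sprintf("psi reduced from %d to the %d available rows", psi, n))
    psi <- n
  }
  hlim <- ceiling(log2(psi))
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, psi)
    trees[[t]] <- grow_itree(X, idx, hlim)
  }
  structure(list(trees = trees, n_trees = n_trees, psi = psi,
                 contamination = contamination,
                 feature_names = colnames(X), seed = seed,
                 cpsi = average_path_normalizer_c(psi)),
            class = "iforest_model")
}

#' @export
print.iforest_model <- function(x, ...) {
  cat(sprintf("<iforest_model> %d trees, psi = %d, %d features%s\n",
              x$n_trees, x$psi, length(x$feature_names),
              if (!is.null(x$calibration)) ", calibrated" else ""))
  invisible(x)
}

#' Isolation path length of a probe in one tree
#'
#' Edges traversed from the root to the external node the probe falls in,
#' plus the `c(size)` adjustment at that node.
#'
#' @param tree a tree matrix from an `iforest_model`.
#' @param x numeric probe vector matching the model's feature arity.
#' @return path length (>= 0).
#' @export
path_length <- function(tree, x) {
  if (length(x) < max(tree[, "feature"])) {
    stop_param("probe arity %d below tree's feature indices", length(x))
  }
  node <- 1L
  depth <- 0
  while (tree[node, "feature"] > 0) {
    f <- tree[node, "feature"]
    node <- if (x[f] < tree[node, "split"]) tree[node, "left"]
    else tree[node, "right"]
    depth <- depth + 1
  }
  depth + as.numeric(tree[node, "cterm"])
}

#' Anomaly score of probes under a fitted model
#'
#' `s = 2^(-E[h(x)] / c(psi))` with the expectation over the ensemble's path
#' lengths: near 1 is anomalous (poor quality), near 0 is normal.
#'
#' @param model an `iforest_model`.
#' @param X probe matrix or vector (feature order must match the model).
#' @return numeric vector of scores in (0, 1).
#' @export
anomaly_score <- function(model, X) {
  if (!inherits(model, "iforest_model")) stop_param("model is not fitted")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    X <- X[, model$feature_names, drop = FALSE]
  }
  if (ncol(X) != length(model$feature_names) && !is.null(model$feature_names)) {
    stop_param("probe has %d features, model expects %d",
               ncol(X), length(model$feature_names))
  }
  eh <- .forest_avg_path(model$trees, X)
  2^(-eh / model$cpsi)
}
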