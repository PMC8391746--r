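test_that("path-length normalizer: conventions, exact c(2), monotonicity", {
  expect_equal(average_path_normalizer_c(0), 0)
  expect_equal(average_path_normalizer_c(1), 0)
  expect_equal(average_path_normalizer_c(2), 1.0)
  n <- 2:2000
  cn <- average_path_normalizer_c(n)
  expect_true(all(diff(cn) > 0))
  # harmonic and approximate regimes agree at the switchover
  expect_equal(average_path_normalizer_c(1000), average_path_normalizer_c(1001),
               tolerance = 3e-3)
  expect_error(average_path_normalizer_c(-1), ">= 0")
})

test_that("degenerate training data: identical rows give equal scores of 0.5", {
  X <- matrix(1, nrow = 40, ncol = 3)
  expect_warning(m <- iforest_fit(X, n_trees = 20, psi = 256, seed = 1), "psi")
  expect_true(all(vapply(m$trees, nrow, 0L) == 1))
  s <- anomaly_score(m, matrix(rnorm(30), 10, 3))
  expect_equal(s, rep(0.5, 10))   # E[h] = 0 + c(psi) exactly
})

test_that("fit is deterministic in the seed", {
  set.seed(99); X <- matrix(rnorm(500 * 4), 500)
  probes <- matrix(rnorm(50 * 4), 50)
  m1 <- iforest_fit(X, n_trees = 50, psi = 64, seed = 5)
  m2 <- iforest_fit(X, n_trees = 50, psi = 64, seed = 5)
  expect_identical(anomaly_score(m1, probes), anomaly_score(m2, probes))
  m3 <- iforest_fit(X, n_trees = 50, psi = 64, seed = 6)
  expect_false(identical(anomaly_score(m1, probes), anomaly_score(m3, probes)))
})

test_that("tree growth and path lengths match the recursive reference", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40)
    psi <- sample(4:8, 1)
    seed <- 100 + rep
    m <- iforest_fit(X, n_trees = 1, psi = psi, seed = seed)
    set.seed(seed)
    idx <- sample.int(nrow(X), psi)
    ref <- ref_grow_tree(X, idx, 0, ceiling(log2(psi)))
    expect_same_tree(m$trees[[1]], ref)
    for (i in 1:20) {
      x <- rnorm(3)
      expect_equal(path_length(m$trees[[1]], x), ref_path_length(ref, x),
                   tolerance = 1e-12)
    }
  }
})

test_that("path_length on hand-built trees, non-negativity", {
  single <- matrix(c(0, 0, 0, 0, 7, average_path_normalizer_c(7)), 1,
                   dimnames = list(NULL, c("feature", "split", "left", "right",
                                           "size", "cterm")))
  expect_equal(path_length(single, 5), average_path_normalizer_c(7))
  tri <- rbind(c(1, 0.5, 2, 3, 5, 0),
               c(0, 0, 0, 0, 2, average_path_normalizer_c(2)),
               c(0, 0, 0, 0, 3, average_path_normalizer_c(3)))
  colnames(tri) <- c("feature", "split", "left", "right", "size", "cterm")
  expect_equal(path_length(tri, 0.2), 1 + average_path_normalizer_c(2))
  expect_equal(path_length(tri, 0.9), 1 + average_path_normalizer_c(3))
  expect_gte(path_length(tri, -1e6), 0)
})

test_that("anomaly score follows the exponential form and its limits", {
  # s = 2^(-E/c); E = c(psi) -> 0.5 is covered by the identical-row fit above
  expect_equal(2^(-0 / 1), 1)   # limiting forms sanity
  set.seed(8)
  X <- rbind(matrix(rnorm(256 * 2), 256), c(12, -12))
  m <- iforest_fit(X, n_trees = 400, psi = 128, seed = 2)
  s <- anomaly_score(m, X)
  expect_equal(which.max(s), 257)
  blob <- s[1:256]
  expect_gt(s[257], mean(blob) + 5 * sd(blob))
  expect_true(all(s > 0 & s < 1))
})

test_that("ensemble scores concentrate across seeds", {
  set.seed(12)
  X <- matrix(rnorm(400 * 3), 400)
  probes <- matrix(rnorm(60 * 3), 60)
  s1 <- anomaly_score(iforest_fit(X, 2000, psi = 128, seed = 1), probes)
  s2 <- anomaly_score(iforest_fit(X, 2000, psi = 128, seed = 2), probes)
  expect_lt(mean(abs(s1 - s2)), 0.02)
})
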