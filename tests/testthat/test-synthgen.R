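test_that("clean ECG generator obeys rate, jitter and determinism contracts", {
  r <- gen_clean_ecg(60, hr_bpm = 60, hrv_frac = 0, seed = 7)
  expect_equal(diff(r$beats), rep(1, length(r$beats) - 1), tolerance = 1e-12)
  expect_true(abs(length(r$beats) - 60) <= 1)
  r2 <- gen_clean_ecg(60, hr_bpm = 60, hrv_frac = 0, seed = 7)
  expect_identical(r$samples, r2$samples)
  r3 <- gen_clean_ecg(60, hr_bpm = 60, hrv_frac = 0.1, seed = 8)
  expect_false(identical(r$samples, r3$samples))
  expect_error(gen_clean_ecg(5), "duration")
  expect_error(gen_clean_ecg(60, hr_bpm = 300), "hr_bpm")
  expect_error(gen_clean_ecg(60, hrv_frac = 0.5), "hrv_frac")
})

test_that("rate modes rescale the beat period globally", {
  tachy <- gen_clean_ecg(30, hr_bpm = 60, hrv_frac = 0, rate_mode = "tachycardia")
  expect_equal(median(diff(tachy$beats)), 0.5, tolerance = 1e-9)
  brady <- gen_clean_ecg(30, hr_bpm = 60, hrv_frac = 0, rate_mode = "bradycardia")
  expect_gt(median(diff(brady$beats)), 1.4)
})

test_that("clean respiration generator: constant periods, apnea, determinism", {
  r <- gen_clean_resp(90, rr_bpm = 12, var_frac = 0, seed = 3)
  expect_equal(diff(r$breath_peaks), rep(5, length(r$breath_peaks) - 1),
               tolerance = 1e-9)
  ra <- gen_clean_resp(90, rr_bpm = 12, var_frac = 0,
                       apnea_spans = list(c(40, 10)), seed = 3)
  t <- (seq_along(ra$samples) - 1) / ra$fs
  inside <- ra$samples[t >= 41 & t < 49]
  outside <- ra$samples[t < 38 | t > 52]
  expect_lt(var(inside), 0.01 * var(outside))
  expect_identical(ra$samples,
                   gen_clean_resp(90, rr_bpm = 12, var_frac = 0,
                                  apnea_spans = list(c(40, 10)), seed = 3)$samples)
  expect_error(gen_clean_resp(90, apnea_spans = list(c(85, 10))), "apnea")
})

test_that("noise injection: identity at zero spec, exact bookkeeping", {
  rec <- gen_clean_ecg(20, seed = 1)
  out <- inject_noise(rec, noise_spec(seed = 5))
  expect_equal(out$samples, rec$samples)

  wn <- inject_noise(rec, noise_spec(bw_rel_amp = 0.5, seed = 5))
  tr <- window_truth(wn, 0)
  expect_equal(tr$wander_ratio, 0.5, tolerance = 0.02)

  dn <- inject_noise(rec, noise_spec(dropout_spans = list(c(2, 3)), seed = 5))
  expect_equal(window_truth(dn, 0)$dropout_s, 3.0)
  # dropout stored as last held value, never NA
  expect_false(anyNA(dn$samples))
  expect_error(inject_noise(rec, noise_spec(dropout_spans = list(c(18, 5)))),
               "duration")
})

test_that("rule-based labeler reproduces the grading criteria rows", {
  expect_equal(label_window(mk_truth("ECG", wander = 0.25)), "good")
  expect_equal(label_window(mk_truth("ECG", dropout = 3.0)), "unacceptable")
  expect_equal(label_window(mk_truth("ECG", dropout = 1.5, wander = 0.6)),
               "acceptable")
  expect_equal(label_window(mk_truth("ECG", impulses = 2L)), "acceptable")
  expect_equal(label_window(mk_truth("ECG", impulses = 3L)), "unacceptable")
  expect_equal(label_window(mk_truth("ECG", unreadable = 3L)), "unacceptable")
  expect_equal(label_window(mk_truth("ECG", wander = 1.2)), "unacceptable")
  expect_equal(label_window(mk_truth("RESP", regular = 0.80)), "good")
  expect_equal(label_window(mk_truth("RESP", regular = 0.40)), "acceptable")
  expect_equal(label_window(mk_truth("RESP", regular = 0.10)), "unacceptable")
  expect_equal(label_window(mk_truth("RESP", apnea = 16)), "unacceptable")
  expect_equal(label_window(mk_truth("RESP", regular = 0.6, apnea = 12)),
               "acceptable")
})

test_that("labeler is total and degradation is monotone", {
  for (w in seq(0, 2, by = 0.25)) {
    for (d in seq(0, 5, by = 0.5)) {
      g1 <- label_window(mk_truth("ECG", wander = w, dropout = d))
      expect_true(g1 %in% c("good", "acceptable", "unacceptable"))
      g2 <- label_window(mk_truth("ECG", wander = w, dropout = d + 0.5))
      g3 <- label_window(mk_truth("ECG", wander = w + 0.25, dropout = d))
      expect_gte(grade_rank(g2), grade_rank(g1))
      expect_gte(grade_rank(g3), grade_rank(g1))
    }
  }
  for (reg in seq(0, 1, by = 0.2)) {
    for (ap in seq(0, 20, by = 5)) {
      g1 <- label_window(mk_truth("RESP", regular = reg, apnea = ap))
      g2 <- label_window(mk_truth("RESP", regular = reg, apnea = ap + 5))
      expect_gte(grade_rank(g2), grade_rank(g1))
    }
  }
})

test_that("dataset builder: disjoint splits, clean config gives all-good labels", {
  ds <- make_dataset("ECG", n_train = 5, n_validation = 30, n_test = 30,
                     mixture = c(good = 1, acceptable = 0, unacceptable = 0),
                     seed = 11)
  expect_true(all(ds$validation$labels$grade == "good"))
  ids <- list(vapply(ds$train, function(r) r$record_id, ""),
              ds$validation$labels$record_id, ds$test$labels$record_id)
  expect_equal(length(intersect(ids[[1]], ids[[2]])), 0)
  expect_equal(length(intersect(ids[[2]], ids[[3]])), 0)
  expect_error(make_dataset("ECG", mixture = c(0.5, 0.2, 0.2)), "mixture")
})

test_that("dataset mixture is realized within tolerance at scale", {
  ds <- make_dataset("ECG", n_train = 5, n_validation = 3000, n_test = 5,
                     seed = 13)
  p <- prop.table(table(factor(ds$validation$labels$grade,
                               c("good", "acceptable", "unacceptable"))))
  expect_lt(abs(p["good"] - 0.8734), 0.03)
  expect_lt(abs(p["acceptable"] - 0.0546), 0.03)
  expect_lt(abs(p["unacceptable"] - 0.0720), 0.03)
})
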