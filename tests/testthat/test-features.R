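test_that("moment features match the direct-moment oracle and closed forms", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(kurtosis(c(-1, 1, -1, 1)), 1.0)
  expect_equal(kurtosis(c(0, 0, 0, 1)), 7 / 3, tolerance = 1e-12)
  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 10))
    expect_equal(skewness(x), oracle_skewness(x), tolerance = 1e-12)
    expect_equal(kurtosis(x), oracle_kurtosis(x), tolerance = 1e-12)
    expect_equal(skewness(rev(x)), skewness(x), tolerance = 1e-12)
  }
  x <- rnorm(1e5)
  expect_equal(kurtosis(x), 3, tolerance = 0.2 / 3)
  expect_error(skewness(rep(1, 10)), "constant")
  expect_error(kurtosis(c(1, 2)), "length")
})

test_that("DTW distance: identity, symmetry, brute-force equality", {
  expect_equal(dtw_distance(c(0, 0, 1, 0), c(0, 1, 0)),
               oracle_dtw(c(0, 0, 1, 0), c(0, 1, 0)))
  set.seed(7)
  for (i in 1:25) {
    a <- round(runif(sample(2:5, 1), -2, 2), 2)
    b <- round(runif(sample(2:5, 1), -2, 2), 2)
    expect_equal(dtw_distance(a, b), oracle_dtw(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
  long <- rnorm(100)
  expect_equal(dtw_distance(long, long), 0)
  expect_gte(dtw_distance(rnorm(30), rnorm(40)), 0)
  expect_error(dtw_distance(numeric(0), 1), "empty")
})

test_that("R-peak detector recovers clean and ectopic beats", {
  rec <- gen_clean_ecg(20, hr_bpm = 60, hrv_frac = 0, seed = 3)
  cw <- first_window(rec)
  det <- detect_r_peaks(cw)
  truth <- rec$beats[rec$beats < 10]
  expect_true(abs(length(det$peaks) - 10) <= 1)
  err <- vapply(truth, function(b) min(abs(det$times - b)), 0)
  expect_lt(max(err), 0.05)

  vpb <- gen_clean_ecg(20, hr_bpm = 60, hrv_frac = 0, seed = 3,
                       ectopic_type = "VPB", ectopic_beat_indices = 5L)
  detv <- detect_r_peaks(first_window(vpb))
  truthv <- vpb$beats[vpb$beats < 10]
  expect_equal(length(detv$peaks), length(truthv))

  flat <- cw; flat$samples <- rep(0, length(flat$samples))
  flat$flags$flatline <- TRUE
  expect_length(detect_r_peaks(flat)$peaks, 0)
})

test_that("breath extrema detector: counts and alternation invariant", {
  rec <- gen_clean_resp(60, rr_bpm = 12, var_frac = 0, seed = 5)
  cw <- first_window(rec)
  ext <- detect_breath_extrema(cw)
  expect_true(abs(length(ext$peaks) - 6) <= 1)
  set.seed(42)
  for (i in 1:10) {
    w <- cw
    w$samples <- cumsum(rnorm(length(cw$samples)))
    w$samples <- w$samples - mean(w$samples)
    e <- detect_breath_extrema(w)
    ev <- rbind(data.frame(t = e$peaks, k = 1), data.frame(t = e$troughs, k = -1))
    ev <- ev[order(ev$t), ]
    if (nrow(ev) > 1) expect_true(all(diff(ev$k) != 0))
  }
  flat <- cw; flat$samples <- rep(0, length(flat$samples))
  flat$flags$flatline <- TRUE
  expect_length(detect_breath_extrema(flat)$peaks, 0)
})

test_that("adjacent-waveform DTW statistics separate ectopy from rhythm", {
  rec <- gen_clean_ecg(20, hr_bpm = 60, hrv_frac = 0, seed = 9)
  cw <- first_window(rec)
  det <- detect_r_peaks(cw)
  st <- adjacent_waveform_dtw_stats(cw, det$peaks)
  beat_energy <- 1  # beats are z-normalized and distances per-sample
  expect_lt(st$mean, 0.05 * beat_energy)
  vpb <- gen_clean_ecg(20, hr_bpm = 60, hrv_frac = 0, seed = 9,
                       ectopic_type = "VPB", ectopic_beat_indices = 5L)
  cv <- first_window(vpb)
  stv <- adjacent_waveform_dtw_stats(cv, detect_r_peaks(cv)$peaks)
  expect_gt(stv$max, 3 * stv$mean)
  st0 <- adjacent_waveform_dtw_stats(cw, det$peaks[1:2], sentinel = 123)
  expect_equal(st0$mean, 123)
  expect_equal(st0$max, 123)
})

test_that("spectral descriptors: band fractions, entropy, dominant frequency", {
  fs <- 200
  t <- (0:1999) / fs
  w <- structure(list(record_id = "w", start_s = 0, length_s = 10, fs = fs,
                      kind = "ECG", samples = sin(2 * pi * 10 * t),
                      flags = list(flatline = FALSE, saturated = FALSE)),
                 class = "obs_window")
  sp <- spectral_features(w)
  expect_gt(sp$inband_frac, 0.95)
  expect_equal(sp$domfreq_hz, 10, tolerance = fs / 512 / 10)
  set.seed(3)
  wn <- w; wn$samples <- rnorm(2000)
  spw <- spectral_features(wn)
  expect_gt(spw$entropy, 0.9 * log(spw$nbins))
  wr <- structure(list(record_id = "w", start_s = 0, length_s = 30, fs = 25,
                       kind = "RESP", samples = sin(2 * pi * 0.2 * (0:749) / 25),
                       flags = list(flatline = FALSE, saturated = FALSE)),
                  class = "obs_window")
  spr <- spectral_features(wr)
  expect_lt(abs(spr$domfreq_hz - 0.2), 25 / 512 + 1e-9)
  expect_gt(spr$inband_frac, 0.9)
})

test_that("feature vectors have fixed arity, finite entries, sentinel on flatline", {
  ecg <- first_window(gen_clean_ecg(20, seed = 21))
  fe <- ecg_feature_vector(ecg)
  expect_length(fe, 8)
  expect_named(fe, feature_names("ECG"))
  expect_true(all(is.finite(fe)))
  expect_identical(fe, ecg_feature_vector(ecg))
  resp <- first_window(gen_clean_resp(60, seed = 21))
  fr <- resp_feature_vector(resp)
  expect_length(fr, 18)
  expect_named(fr, feature_names("RESP"))
  expect_true(all(is.finite(fr)))
  flat <- ecg; flat$flags$flatline <- TRUE
  ff <- ecg_feature_vector(flat)
  expect_equal(unname(ff["dtw_mean"]), 10)
  ds <- make_dataset("ECG", n_train = 4, n_validation = 4, n_test = 4, seed = 2)
  fm <- extract_features(ds$train)
  expect_equal(nrow(fm), 4)
  expect_true(all(is.finite(as.matrix(fm[, feature_names("ECG")]))))
})
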