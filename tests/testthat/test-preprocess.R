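mk_window <- function(samples, fs, kind = "ECG") {
  structure(list(record_id = "w", start_s = 0,
                 length_s = length(samples) / fs, fs = fs, kind = kind,
                 samples = samples,
                 flags = list(flatline = FALSE, saturated = FALSE)),
            class = "obs_window")
}

test_that("segmentation yields fixed windows and drops the remainder", {
  expect_length(segment_windows(gen_clean_ecg(60, seed = 1)), 6)
  expect_length(segment_windows(gen_clean_ecg(65, seed = 1)), 6)
  expect_length(segment_windows(gen_clean_resp(90, seed = 1)), 3)
  short <- gen_clean_resp(30, seed = 1)
  short$samples <- short$samples[1:600]   # 24 s at 25 Hz
  expect_warning(w <- segment_windows(short), "shorter")
  expect_length(w, 0)
  w5 <- segment_windows(gen_clean_ecg(30, seed = 1), stride_s = 5)
  expect_equal(vapply(w5, `[[`, 0, "start_s"), seq(0, 20, 5))
  expect_equal(length(w5[[1]]$samples), 2000)
})

test_that("band-pass attenuates out-of-band tones and preserves in-band ones", {
  fs <- 200
  t <- (0:1999) / fs
  tone50 <- bandpass(mk_window(sin(2 * pi * 50 * t), fs))
  expect_lt(sqrt(mean(tone50$samples^2)), 0.1 * sqrt(0.5))
  dc <- bandpass(mk_window(rep(2, 2000) + sin(2 * pi * 10 * t), fs))
  expect_lt(abs(mean(dc$samples)), 0.05)
  tone10 <- bandpass(mk_window(sin(2 * pi * 10 * t), fs))
  mid <- 500:1500  # ignore filter edge transients
  expect_equal(max(abs(tone10$samples[mid])), 1, tolerance = 0.05)
  expect_error(bandpass(mk_window(rnorm(750), 25, "RESP"), band = c(0.5, 40)),
               "infeasible")
})

test_that("outlier clipping bounds impulses and leaves ordinary samples alone", {
  set.seed(2)
  x <- rnorm(2000)
  w <- mk_window(x, 200)
  expect_equal(clip_outliers(w)$samples, x)   # nothing beyond the bound
  xi <- x; xi[1000] <- 50
  wc <- clip_outliers(mk_window(xi, 200))
  expect_lt(wc$samples[1000], 50)
  expect_equal(wc$samples[-1000], xi[-1000])
  wconst <- clip_outliers(mk_window(rep(3, 2000), 200))
  expect_equal(wconst$samples, rep(3, 2000))
})

test_that("normalization: zero mean, unit SD, idempotent, flatline flagged", {
  w <- normalize_window(mk_window(rnorm(2000, 5, 3), 200))
  expect_lt(abs(mean(w$samples)), 1e-9)
  expect_equal(sd(w$samples), 1, tolerance = 1e-9)
  expect_false(w$flags$flatline)
  w2 <- normalize_window(w)
  expect_equal(w2$samples, w$samples, tolerance = 1e-9)
  wf <- normalize_window(mk_window(rep(1.5, 2000), 200))
  expect_true(wf$flags$flatline)
  expect_equal(wf$samples, rep(0, 2000))
})

test_that("conditioning pipeline preserves length and finiteness", {
  for (rec in list(gen_clean_ecg(20, seed = 4),
                   gen_clean_resp(60, seed = 4))) {
    noisy <- inject_noise(rec, noise_spec(bw_rel_amp = 0.8,
                                          powerline_rel_amp = 0.2,
                                          impulse_times = c(3, 7), seed = 2))
    for (w in segment_windows(noisy)) {
      cw <- condition_window(w)
      expect_length(cw$samples, length(w$samples))
      expect_true(all(is.finite(cw$samples)))
    }
  }
  # full-window dropout becomes a flagged flatline
  rec <- gen_clean_ecg(30, seed = 5)
  dead <- inject_noise(rec, noise_spec(dropout_spans = list(c(10, 10)), seed = 1))
  w2 <- condition_window(segment_windows(dead)[[2]])
  expect_true(w2$flags$flatline)
})
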