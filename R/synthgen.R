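# Synthetic ECG / respiration generator with parameterized noise injection
# and a rule-based quality labeler. Every generator is a pure function of its
# arguments including the seed, and the realized noise components are kept so
# per-window ground truth (and hence the quality grade) is computable by rule.

#' Noise specification for synthetic corruption
#'
#' Describes the corruption to apply to a clean record: additive baseline
#' wander, mains interference, broadband EMG bursts, impulse artifacts and
#' flatline signal loss. All amplitudes are relative to the clean record's
#' peak-to-peak amplitude.
#'
#' @param bw_rel_amp baseline-wander peak amplitude as a fraction of the clean
#'   peak-to-peak amplitude (>= 0).
#' @param bw_freq_hz length-2 wander frequency band in Hz.
#' @param powerline_rel_amp mains-interference amplitude fraction (>= 0).
#' @param powerline_hz mains frequency (default 50 Hz).
#' @param emg_rel_amp broadband-burst noise level fraction (>= 0).
#' @param emg_burst_spans list of `c(start_s, duration_s)` EMG burst spans.
#' @param impulse_times numeric vector of impulse artifact instants (s).
#' @param impulse_rel_amp impulse height fraction (default 2.5).
#' @param dropout_spans list of `c(start_s, duration_s)` flatline spans.
#' @param seed integer seed for the stochastic components.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(bw_rel_amp = 0, bw_freq_hz = c(0.05, 0.5),
                       powerline_rel_amp = 0, powerline_hz = 50,
                       emg_rel_amp = 0, emg_burst_spans = list(),
                       impulse_times = numeric(0), impulse_rel_amp = 2.5,
                       dropout_spans = list(), seed = 1L) {
  rel <- c(bw_rel_amp, powerline_rel_amp, emg_rel_amp, impulse_rel_amp)
  if (any(!is.finite(rel)) || any(rel < 0)) {
    stop_param("relative noise amplitudes must be finite and >= 0")
  }
  chk_spans <- function(spans, what) {
    if (length(spans) == 0) return(list())
    spans <- lapply(spans, as.numeric)
    if (any(vapply(spans, length, 1L) != 2)) {
      stop_param("%s spans must be c(start_s, duration_s) pairs", what)
    }
    if (any(vapply(spans, function(s) s[1] < 0 || s[2] <= 0, TRUE))) {
      stop_param("%s spans must have start >= 0 and duration > 0", what)
    }
    st <- vapply(spans, `[`, 0, 1)
    en <- st + vapply(spans, `[`, 0, 2)
    o <- order(st)
    if (any(st[o][-1] < en[o][-length(en)])) {
      stop_param("%s spans must be non-overlapping", what)
    }
    spans[o]
  }
  structure(list(
    bw_rel_amp = bw_rel_amp, bw_freq_hz = bw_freq_hz,
    powerline_rel_amp = powerline_rel_amp, powerline_hz = powerline_hz,
    emg_rel_amp = emg_rel_amp,
    emg_burst_spans = chk_spans(emg_burst_spans, "EMG"),
    impulse_times = sort(as.numeric(impulse_times)),
    impulse_rel_amp = impulse_rel_amp,
    dropout_spans = chk_spans(dropout_spans, "dropout"),
    seed = as.integer(seed)
  ), class = "noise_spec")
}

# sum-of-Gaussians beat morphology; offsets/widths are fractions of the beat
# period so morphology compresses plausibly at fast rates
ecg_beat_shape <- function(t_rel, period, type = "normal") {
  g <- function(mu, sig, amp) amp * exp(-0.5 * ((t_rel - mu * period) / (sig * period))^2)
  if (type == "VPB") {
    # wide, large-amplitude ventricular complex; no P wave, discordant T
    g(0, 0.038, 1.8) + g(0.20, 0.07, -0.5)
  } else {
    g(-0.22, 0.025, 0.15) +   # P
      g(-0.028, 0.010, -0.12) + # Q
      g(0, 0.012, 1.0) +        # R
      g(0.030, 0.010, -0.2) +   # S
      g(0.26, 0.055, 0.35)      # T
  }
}

#' Generate a clean synthetic single-lead ECG
#'
#' Quasi-periodic P-QRS-T waveform built from a sum-of-Gaussians beat template
#' repeated on a jittered beat grid. Ectopic beats (ventricular or atrial
#' premature beats) replace a normal slot prematurely, with a compensatory
#' pause. Ground-truth beat instants and types are attached to the record.
#'
#' @param duration_s record length in seconds (>= 10).
#' @param fs sampling rate in Hz.
#' @param hr_bpm mean heart rate (30--220).
#' @param hrv_frac fractional beat-to-beat period jitter in `[0, 0.3)`.
#' @param seed integer seed.
#' @param record_id identifier.
#' @param ectopic_type `"none"`, `"VPB"` or `"APB"`.
#' @param ectopic_beat_indices 1-based beat slots replaced by ectopic beats.
#' @param rate_mode `"normal"`, `"tachycardia"` (period halved) or
#'   `"bradycardia"` (period / 0.65).
#' @return a `signal_record` with fields `beats` (R-wave instants, s),
#'   `beat_types`, and `amp_ref` (clean peak-to-peak amplitude).
#' @export
gen_clean_ecg <- function(duration_s, fs = 200, hr_bpm = 60, hrv_frac = 0.05,
                          seed = 1L, record_id = "ecg",
                          ectopic_type = c("none", "VPB", "APB"),
                          ectopic_beat_indices = integer(0),
                          rate_mode = c("normal", "tachycardia", "bradycardia")) {
  ectopic_type <- match.arg(ectopic_type)
  rate_mode <- match.arg(rate_mode)
  if (duration_s < 10) stop_param("duration_s must be >= 10, got %g", duration_s)
  if (hr_bpm < 30 || hr_bpm > 220) stop_param("hr_bpm must be in [30, 220]")
  if (hrv_frac < 0 || hrv_frac >= 0.3) stop_param("hrv_frac must be in [0, 0.3)")
  hr_eff <- switch(rate_mode, normal = hr_bpm, tachycardia = 2 * hr_bpm,
                   bradycardia = 0.65 * hr_bpm)
  period <- 60 / hr_eff

  set.seed(seed)
  n_max <- ceiling(duration_s / (period * (1 - hrv_frac))) + 4
  jitter <- if (hrv_frac > 0) runif(n_max, -hrv_frac, hrv_frac) else rep(0, n_max)
  periods <- period * (1 + jitter)
  # ectopic slot arrives prematurely; the following interval is lengthened
  # (compensatory pause) so the grid re-synchronizes
  types <- rep("normal", n_max)
  if (ectopic_type != "none" && length(ectopic_beat_indices) > 0) {
    idx <- as.integer(ectopic_beat_indices)
    if (any(idx < 2 | idx > n_max)) stop_param("ectopic_beat_indices out of range")
    types[idx] <- ectopic_type
    periods[idx - 1] <- periods[idx - 1] * 0.60
    periods[idx] <- periods[idx] * 1.40
  }
  beats <- 0.35 + cumsum(c(0, periods))
  keep <- beats < duration_s - 0.05
  beats <- beats[keep]
  types <- types[seq_along(beats)]

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (k in seq_along(beats)) {
    p <- if (k < length(beats)) beats[k + 1] - beats[k] else period
    # evaluate the template only on a local support around the beat
    lo <- max(1L, floor((beats[k] - 0.45 * max(p, period)) * fs) + 1L)
    hi <- min(n, ceiling((beats[k] + 0.55 * max(p, period)) * fs) + 1L)
    sel <- lo:hi
    x[sel] <- x[sel] + ecg_beat_shape(t[sel] - beats[k], max(p, 0.28), types[k])
  }
  signal_record(x, fs, "ECG", record_id = record_id,
                beats = beats, beat_types = types,
                hr_bpm = hr_eff, amp_ref = diff(range(x)))
}

#' Generate a clean synthetic respiration waveform
#'
#' Smooth quasi-sinusoidal breathing with per-breath period and amplitude
#' jitter; near-flat signal inside apnea (breath-hold) spans. Breath peak and
#' trough instants outside apnea are attached as ground truth.
#'
#' @param duration_s record length in seconds (>= 30).
#' @param fs sampling rate in Hz.
#' @param rr_bpm mean respiratory rate, breaths/min (5--40).
#' @param var_frac fractional breath-to-breath period/amplitude jitter.
#' @param apnea_spans list of `c(start_s, duration_s)` breath-hold spans.
#' @param seed integer seed.
#' @param record_id identifier.
#' @return a `signal_record` with fields `breath_peaks`, `breath_troughs`,
#'   `apnea_spans`, `var_frac`, `amp_ref`.
#' @export
gen_clean_resp <- function(duration_s, fs = 25, rr_bpm = 15, var_frac = 0.05,
                           apnea_spans = list(), seed = 1L,
                           record_id = "resp") {
  if (duration_s < 30) stop_param("duration_s must be >= 30, got %g", duration_s)
  if (rr_bpm < 5 || rr_bpm > 40) stop_param("rr_bpm must be in [5, 40]")
  if (var_frac < 0 || var_frac >= 0.5) stop_param("var_frac must be in [0, 0.5)")
  if (length(apnea_spans) > 0) {
    ends <- vapply(apnea_spans, function(s) s[1] + s[2], 0)
    if (any(vapply(apnea_spans, `[`, 0, 1) < 0) || any(ends > duration_s)) {
      stop_param("apnea spans must lie inside [0, duration_s]")
    }
  }
  period <- 60 / rr_bpm
  set.seed(seed)
  n_breaths <- ceiling(duration_s / (period * (1 - var_frac))) + 2
  jit <- if (var_frac > 0) runif(n_breaths, -var_frac, var_frac) else rep(0, n_breaths)
  periods <- period * (1 + jit)
  amps <- 1 + (if (var_frac > 0) runif(n_breaths, -var_frac, var_frac) else rep(0, n_breaths))
  starts <- cumsum(c(0, periods))[seq_len(n_breaths)]

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  peaks <- troughs <- numeric(0)
  for (k in seq_len(n_breaths)) {
    if (starts[k] >= duration_s) break
    sel <- which(t >= starts[k] & t < starts[k] + periods[k])
    if (length(sel)) {
      x[sel] <- amps[k] * sin(2 * pi * (t[sel] - starts[k]) / periods[k])
    }
    pk <- starts[k] + periods[k] / 4
    tr <- starts[k] + 3 * periods[k] / 4
    if (pk < duration_s) peaks <- c(peaks, pk)
    if (tr < duration_s) troughs <- c(troughs, tr)
  }
  # attenuate inside apnea spans with a short cosine ramp (breath hold)
  env <- rep(1, n)
  ramp <- 0.3
  for (sp in apnea_spans) {
    a <- sp[1]; b <- sp[1] + sp[2]
    env <- pmin(env, ifelse(
      t < a - ramp | t > b + ramp, 1,
      ifelse(t < a, 0.5 - 0.5 * cos(pi * (a - t) / ramp),
             ifelse(t > b, 0.5 - 0.5 * cos(pi * (t - b) / ramp), 0.02))))
    in_ap <- function(z) z >= a & z <= b
    peaks <- peaks[!in_ap(peaks)]
    troughs <- troughs[!in_ap(troughs)]
  }
  x <- x * pmax(env, 0.02)
  signal_record(x, fs, "RESP", record_id = record_id,
                breath_peaks = peaks, breath_troughs = troughs,
                apnea_spans = apnea_spans, var_frac = var_frac,
                amp_ref = diff(range(x)))
}

span_overlap_s <- function(spans, w_start, w_end) {
  if (length(spans) == 0) return(0)
  sum(vapply(spans, function(sp) {
    max(0, min(sp[1] + sp[2], w_end) - max(sp[1], w_start))
  }, 0))
}

#' Inject noise into a clean record
#'
#' Adds baseline wander (band-limited random walk plus a slow sinusoid, scaled
#' to the requested peak ratio), mains interference, broadband EMG bursts and
#' impulse artifacts, then overwrites dropout spans with the last held value.
#' The realized additive components are attached so per-window ground truth is
#' computable exactly.
#'
#' @param record a clean (or previously corrupted) `signal_record`.
#' @param noise a [noise_spec()].
#' @return a `signal_record` with extra fields `clean`, `wander`, `hf_noise`
#'   (powerline + EMG + impulses), `noise` (the spec) and `amp_ref`.
#' @export
inject_noise <- function(record, noise) {
  stopifnot(inherits(record, "signal_record"), inherits(noise, "noise_spec"))
  n <- length(record$samples)
  fs <- record$fs
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  for (sp in c(noise$emg_burst_spans, noise$dropout_spans)) {
    if (sp[1] + sp[2] > dur + 1e-9) stop_param("noise span exceeds record duration")
  }
  if (length(noise$impulse_times) && any(noise$impulse_times >= dur)) {
    stop_param("impulse times must lie inside the record")
  }
  amp_ref <- record$amp_ref
  if (is.null(amp_ref)) amp_ref <- diff(range(record$samples))
  set.seed(noise$seed)

  wander <- numeric(n)
  if (noise$bw_rel_amp > 0) {
    rw <- cumsum(rnorm(n))
    k <- max(3L, round(fs / (2 * mean(noise$bw_freq_hz))))
    rw <- as.numeric(stats::filter(rw, rep(1 / k, k), sides = 2))
    rw[is.na(rw)] <- 0
    f0 <- runif(1, noise$bw_freq_hz[1], noise$bw_freq_hz[2])
    w <- rw / max(abs(rw), 1e-12) + 0.8 * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
    # scale to the requested peak ratio per observation window, so the
    # per-window ground truth equals the requested amplitude exactly
    wlen_n <- round(window_length_s(record$kind) * fs)
    wander <- w
    for (i0 in seq(1, n, by = wlen_n)) {
      sel <- i0:min(n, i0 + wlen_n - 1)
      pk <- max(abs(w[sel]))
      if (pk > 0) wander[sel] <- w[sel] / pk * noise$bw_rel_amp * amp_ref
    }
  }

  hf <- numeric(n)
  if (noise$powerline_rel_amp > 0) {
    hf <- hf + noise$powerline_rel_amp * amp_ref *
      sin(2 * pi * noise$powerline_hz * t + runif(1, 0, 2 * pi))
  }
  for (sp in noise$emg_burst_spans) {
    sel <- which(t >= sp[1] & t < sp[1] + sp[2])
    if (length(sel)) {
      hf[sel] <- hf[sel] + rnorm(length(sel), sd = noise$emg_rel_amp * amp_ref / 4)
    }
  }
  half_w <- max(1L, round(0.015 * fs))   # ~30 ms triangular impulse
  for (ti in noise$impulse_times) {
    ci <- round(ti * fs) + 1L
    sel <- max(1L, ci - half_w):min(n, ci + half_w)
    tri <- 1 - abs(sel - ci) / (half_w + 1)
    sgn <- if (runif(1) < 0.5) -1 else 1
    hf[sel] <- hf[sel] + sgn * noise$impulse_rel_amp * amp_ref * tri
  }

  x <- record$samples + wander + hf
  for (sp in noise$dropout_spans) {
    sel <- which(t >= sp[1] & t < sp[1] + sp[2])
    if (length(sel)) x[sel] <- x[max(1L, sel[1] - 1L)]
  }

  out <- record
  out$clean <- record$samples
  out$samples <- x
  out$wander <- wander
  out$hf_noise <- hf
  out$noise <- noise
  out$amp_ref <- amp_ref
  out
}

#' Ground truth for one observation window
#'
#' Aggregates the realized noise components of a corrupted record over a
#' single window into the quantities the rule-based labeler thresholds.
#'
#' @param record a record returned by [inject_noise()] (or a clean generator
#'   record, in which case all noise quantities are zero).
#' @param start_s window start (s).
#' @param jitter_bound breath-period jitter above which the respiratory
#'   waveform is not counted as regular.
#' @param snr_threshold beat local signal-to-noise ratio below which an ECG
#'   beat counts as unreadable.
#' @return a `ground_truth` list.
#' @export
window_truth <- function(record, start_s = 0, jitter_bound = 0.25,
                         snr_threshold = 2) {
  len <- window_length_s(record$kind)
  w_end <- start_s + len
  fs <- record$fs
  ns <- noise_or_null(record)
  wander <- record$wander
  sel <- which((seq_along(record$samples) - 1) / fs >= start_s &
                 (seq_along(record$samples) - 1) / fs < w_end)
  wander_ratio <- if (is.null(wander)) 0 else {
    max(abs(wander[sel])) / record$amp_ref
  }
  n_impulses <- if (is.null(ns)) 0L else {
    sum(ns$impulse_times >= start_s & ns$impulse_times < w_end)
  }
  dropout_s <- if (is.null(ns)) 0 else {
    span_overlap_s(ns$dropout_spans, start_s, w_end)
  }
  emg_s <- if (is.null(ns)) 0 else {
    span_overlap_s(ns$emg_burst_spans, start_s, w_end)
  }
  emg_rel <- if (is.null(ns) || emg_s == 0) 0 else ns$emg_rel_amp

  out <- list(kind = record$kind, start_s = start_s, length_s = len,
              wander_ratio = wander_ratio, n_impulses = n_impulses,
              dropout_s = min(dropout_s, len), emg_s = emg_s,
              emg_rel = emg_rel)

  if (record$kind == "ECG") {
    beats <- record$beats[record$beats >= start_s & record$beats < w_end]
    unreadable <- 0L
    if (!is.null(record$hf_noise) && length(beats)) {
      for (b in beats) {
        lsel <- which((seq_along(record$samples) - 1) / fs >= b - 0.15 &
                        (seq_along(record$samples) - 1) / fs < b + 0.15)
        noise_sd <- sd(record$hf_noise[lsel])
        if (is.finite(noise_sd) && noise_sd > 0) {
          snr <- (record$amp_ref / 2) / (2 * noise_sd)
          if (snr < snr_threshold) unreadable <- unreadable + 1L
        }
      }
    }
    out$n_beats <- length(beats)
    out$unreadable_beats <- unreadable
    out$ectopic <- !is.null(record$beat_types) && any(record$beat_types != "normal")
  } else {
    apnea_s <- span_overlap_s(record$apnea_spans, start_s, w_end)
    excluded <- apnea_s + dropout_s + emg_s
    var_frac <- if (is.null(record$var_frac)) 0 else record$var_frac
    regular <- if (var_frac > jitter_bound) 0 else max(0, (len - excluded) / len)
    out$apnea_s <- apnea_s
    out$regular_fraction <- regular
  }
  structure(out, class = "ground_truth")
}

noise_or_null <- function(record) {
  if (is.null(record$noise)) NULL else record$noise
}

#' Rule-based quality grade from ground truth
#'
#' Applies the quantitative grading rules for one observation window and
#' returns the worst grade any clause triggers. ECG: signal loss over 2 s,
#' wander at or above the signal amplitude, more than 2 unreadable beats or
#' more than 2 impulse artifacts are unacceptable; any signal loss up to 2 s,
#' wander at or above one-third of the signal amplitude, 1--2 impulses, up to
#' 2 unreadable beats or a low-intensity EMG burst are acceptable; otherwise
#' good. RESP: a regular waveform over three-fourths of the window with
#' wander below the signal amplitude is good; a recognizable rhythm (regular
#' fraction at least one-fourth) with signal loss or breath hold under half
#' the window is acceptable; otherwise unacceptable. Pathological beats never
#' degrade the grade.
#'
#' @param truth a `ground_truth` from [window_truth()].
#' @return `"good"`, `"acceptable"` or `"unacceptable"`.
#' @export
label_window <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$kind == "ECG") {
    if (truth$dropout_s > 2 || truth$wander_ratio >= 1 ||
        truth$n_impulses > 2 || truth$unreadable_beats > 2) {
      return("unacceptable")
    }
    if (truth$dropout_s > 0 || truth$wander_ratio >= 1 / 3 ||
        truth$n_impulses >= 1 || truth$unreadable_beats >= 1 ||
        (truth$emg_s > 0 && truth$emg_rel > 0.05)) {
      return("acceptable")
    }
    "good"
  } else if (truth$kind == "RESP") {
    half <- truth$length_s / 2
    loss_s <- truth$dropout_s + truth$apnea_s
    if (truth$regular_fraction < 0.25 || loss_s >= half ||
        truth$wander_ratio >= 2) {
      return("unacceptable")
    }
    if (truth$regular_fraction > 0.75 && truth$wander_ratio < 1 &&
        loss_s < truth$length_s / 4) {
      return("good")
    }
    "acceptable"
  } else {
    stop_param("unknown signal kind %s", truth$kind)
  }
}

# Draw a one-window noise scenario engineered to trigger a target grade.
# Labels downstream always come from the realized ground truth, never from
# the intent; these ranges just set the severity mixture.
scenario_noise <- function(kind, grade, dur, seed) {
  set.seed(seed)
  sub_seed <- sample.int(2^30, 1)
  sp <- function(lo_len, hi_len) {
    len <- runif(1, lo_len, hi_len)
    st <- runif(1, 0.3, dur - len - 0.3)
    list(c(st, len))
  }
  if (kind == "ECG") {
    if (grade == "good") {
      if (runif(1) < 0.5) noise_spec(seed = sub_seed)
      else noise_spec(bw_rel_amp = runif(1, 0.05, 0.28),
                      powerline_rel_amp = runif(1, 0, 0.03), seed = sub_seed)
    } else if (grade == "acceptable") {
      pick <- sample(4, 1)
      switch(pick,
        noise_spec(bw_rel_amp = runif(1, 0.40, 0.90), seed = sub_seed),
        noise_spec(dropout_spans = sp(0.5, 1.8), seed = sub_seed),
        noise_spec(impulse_times = sort(runif(sample(2, 1), 0.5, dur - 0.5)),
                   seed = sub_seed),
        noise_spec(emg_rel_amp = runif(1, 0.12, 0.25),
                   emg_burst_spans = sp(1.5, 3.5), seed = sub_seed))
    } else {
      pick <- sample(4, 1)
      switch(pick,
        noise_spec(dropout_spans = sp(2.5, 6), seed = sub_seed),
        noise_spec(bw_rel_amp = runif(1, 1.05, 1.8), seed = sub_seed),
        noise_spec(impulse_times = sort(runif(sample(3:6, 1), 0.5, dur - 0.5)),
                   seed = sub_seed),
        noise_spec(emg_rel_amp = runif(1, 0.9, 1.6),
                   emg_burst_spans = sp(0.7 * dur, 0.85 * dur), seed = sub_seed))
    }
  } else {
    if (grade == "good") {
      if (runif(1) < 0.5) noise_spec(seed = sub_seed)
      else noise_spec(bw_rel_amp = runif(1, 0.1, 0.6), seed = sub_seed)
    } else if (grade == "acceptable") {
      if (runif(1) < 0.5) noise_spec(bw_rel_amp = runif(1, 1.1, 1.8), seed = sub_seed)
      else noise_spec(dropout_spans = sp(8, 13), seed = sub_seed)
    } else {
      pick <- sample(3, 1)
      switch(pick,
        noise_spec(dropout_spans = sp(16, 24), seed = sub_seed),
        noise_spec(bw_rel_amp = runif(1, 2.1, 3.5), seed = sub_seed),
        noise_spec(emg_rel_amp = runif(1, 1.2, 2.0),
                   emg_burst_spans = sp(0.8 * dur, 0.9 * dur), seed = sub_seed))
    }
  }
}

# generate one single-window record for the dataset builder; apnea scenarios
# for RESP acceptable/unacceptable grades are realized through the clean
# generator's apnea spans rather than dropouts half the time
dataset_record <- function(kind, grade, id, seed) {
  dur <- window_length_s(kind)
  set.seed(seed)
  s_clean <- sample.int(2^30, 1)
  s_noise <- sample.int(2^30, 1)
  if (kind == "ECG") {
    hr <- runif(1, 55, 95)
    ect <- grade == "good" && runif(1) < 0.10
    rec <- gen_clean_ecg(dur, hr_bpm = hr, hrv_frac = runif(1, 0.02, 0.08),
                         seed = s_clean, record_id = id,
                         ectopic_type = if (ect) "VPB" else "none",
                         ectopic_beat_indices = if (ect) 5L else integer(0))
  } else {
    rr <- runif(1, 10, 22)
    apnea <- list()
    if (grade == "acceptable" && runif(1) < 0.5) {
      len <- runif(1, 8, 13); apnea <- list(c(runif(1, 1, dur - len - 1), len))
      grade <- "good"  # noise side stays mild; apnea drives the label
    } else if (grade == "unacceptable" && runif(1) < 0.4) {
      len <- runif(1, 16, 24); apnea <- list(c(runif(1, 1, dur - len - 1), len))
      grade <- "good"
    }
    rec <- gen_clean_resp(dur, rr_bpm = rr, var_frac = runif(1, 0.02, 0.10),
                          apnea_spans = apnea, seed = s_clean, record_id = id)
  }
  inject_noise(rec, scenario_noise(kind, grade, dur, s_noise))
}

#' Build a synthetic train / validation / test dataset
#'
#' Generates single-window records: an unlabeled training set dominated by
#' clean or mildly noisy signal (the anomaly-detection premise that anomalies
#' are few), and labeled validation and test sets with a configurable grade
#' mixture. Labels are always derived from the realized noise ground truth by
#' [label_window()]; the mixture controls only the severity of the injected
#' scenarios. The three splits share no record id.
#'
#' @param kind `"ECG"` or `"RESP"`.
#' @param n_train,n_validation,n_test window counts per split.
#' @param mixture length-3 named target proportions for
#'   good/acceptable/unacceptable in the labeled splits; defaults to the
#'   package's documented benchmark mixtures (ECG 87.3/5.5/7.2 %,
#'   RESP 62.7/24.5/12.8 %).
#' @param train_good_frac fraction of training windows drawn from the clean
#'   scenario (default 0.92).
#' @param seed master seed.
#' @return a list with `train` (list of records), `validation` and `test`
#'   (each a list with `records` and a `labels` data frame of
#'   `record_id, window_start_s, window_len_s, grade`).
#' @export
make_dataset <- function(kind = c("ECG", "RESP"), n_train = 500,
                         n_validation = 500, n_test = 500,
                         mixture = NULL, train_good_frac = 0.92, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(mixture)) {
    mixture <- if (kind == "ECG") c(good = 0.8734, acceptable = 0.0546,
                                    unacceptable = 0.0720)
    else c(good = 0.6270, acceptable = 0.2450, unacceptable = 0.1280)
  }
  if (length(mixture) != 3 || any(mixture < 0) || abs(sum(mixture) - 1) > 1e-6) {
    stop_param("mixture must be 3 non-negative proportions summing to 1")
  }
  if (train_good_frac < 0.5) stop_param("training set must be mostly clean")
  set.seed(seed)
  seeds <- sample.int(2^30, n_train + n_validation + n_test)
  build_split <- function(prefix, n, grades, off) {
    recs <- vector("list", n)
    labs <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%05d", prefix, i)
      recs[[i]] <- dataset_record(kind, grades[i], id, seeds[off + i])
      truth <- window_truth(recs[[i]])
      labs[[i]] <- data.frame(record_id = id, window_start_s = 0,
                              window_len_s = window_length_s(kind),
                              grade = label_window(truth),
                              stringsAsFactors = FALSE)
    }
    list(records = recs, labels = do.call(rbind, labs))
  }
  tr_grades <- ifelse(runif(n_train) < train_good_frac, "good", "acceptable")
  train <- build_split("train", n_train, tr_grades, 0)
  val_grades <- sample(GRADES, n_validation, replace = TRUE, prob = mixture)
  validation <- build_split("val", n_validation, val_grades, n_train)
  test_grades <- sample(GRADES, n_test, replace = TRUE, prob = mixture)
  test <- build_split("test", n_test, test_grades, n_train + n_validation)
  list(kind = kind, train = train$records,
       validation = validation, test = test)
}
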