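# Feature extraction: distribution moments (population convention),
# adjacent-waveform DTW distances, beat/breath segmentation and Welch-style
# spectral descriptors, assembled into fixed-order feature vectors
# (8 for ECG, 18 for RESP).

#' Skewness (population convention)
#'
#' Third standardized central moment with the biased (divide-by-N) estimator
#' and the population standard deviation, i.e.
#' `mean((x - mean(x))^3) / sd_pop(x)^3`.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return skewness value.
#' @export
skewness <- function(x) {
  if (length(x) < 3) stop_param("skewness needs length >= 3")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) stop_param("skewness undefined for constant input")
  mean((x - m)^3) / s2^1.5
}

#' Kurtosis (population convention, non-excess)
#'
#' Fourth standardized central moment `mean((x - mean(x))^4) / sd_pop(x)^4`,
#' without the excess (-3) correction; a normal sample gives ~3.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return kurtosis value.
#' @export
kurtosis <- function(x) {
  if (length(x) < 3) stop_param("kurtosis needs length >= 3")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) stop_param("kurtosis undefined for constant input")
  mean((x - m)^4) / s2^2
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with absolute-difference local cost and an
#' unconstrained (full) warping window; symmetric and zero on identical
#' inputs.
#'
#' @param a,b non-empty numeric vectors.
#' @return the cumulative alignment cost (>= 0).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop_param("dtw_distance: empty input")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_param("dtw_distance: non-finite input")
  }
  .dtw_dp(as.numeric(a), as.numeric(b))
}

#' Detect R peaks in a conditioned ECG window
#'
#' Derivative-square-integrate detector: the squared first difference is
#' integrated over a 150 ms moving window, candidate maxima above an adaptive
#' threshold are accepted greedily under a refractory period, and each
#' accepted peak is refined to the local waveform maximum.
#'
#' @param window a conditioned ECG `obs_window` (or any numeric vector via
#'   `samples`/`fs` arguments of the internal path).
#' @param refractory_s minimum peak separation (default 0.25 s).
#' @return list with `peaks` (sample indices, strictly increasing) and
#'   `times` (seconds from window start); both empty on flat or pure-noise
#'   input.
#' @export
detect_r_peaks <- function(window, refractory_s = 0.25) {
  stopifnot(inherits(window, "obs_window"))
  x <- window$samples
  fs <- window$fs
  if (window$flags$flatline || sd(x) == 0) {
    return(list(peaks = integer(0), times = numeric(0)))
  }
  d <- c(0, diff(x))
  sq <- d^2
  k <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / k, k), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.20 * quantile(integ, 0.98)
  if (thr <= 0) return(list(peaks = integer(0), times = numeric(0)))
  cand <- which(integ > thr)
  # second candidate pass on raw amplitude so wide large complexes (e.g.
  # ventricular ectopy) with little derivative energy are not missed
  ax <- abs(x)
  n <- length(x)
  athr <- 0.45 * quantile(ax, 0.995)
  if (athr > 0 && n > 2) {
    loc <- which(ax[2:(n - 1)] >= ax[1:(n - 2)] & ax[2:(n - 1)] >= ax[3:n] &
                   ax[2:(n - 1)] > athr) + 1L
    cand <- union(cand, loc)
  }
  if (!length(cand)) return(list(peaks = integer(0), times = numeric(0)))
  cand <- cand[order(integ[cand], decreasing = TRUE)]
  refr <- round(refractory_s * fs)
  accepted <- integer(0)
  for (ci in cand) {
    if (!length(accepted) || all(abs(accepted - ci) >= refr)) {
      accepted <- c(accepted, ci)
    }
  }
  # refine to the local maximum of the waveform around each candidate
  half <- round(0.10 * fs)
  peaks <- vapply(accepted, function(ci) {
    lo <- max(1L, ci - half); hi <- min(length(x), ci + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, 0L)
  peaks <- sort(unique(peaks))
  # drop refinements that collapsed within the refractory period
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refr)
    peaks <- peaks[keep]
  }
  list(peaks = peaks, times = (peaks - 1) / fs)
}

#' Detect breath peaks and troughs in a conditioned respiration window
#'
#' Local extrema of the smoothed waveform with a minimum breath period of
#' 1.5 s; an alternating peak/trough sequence is enforced by keeping the more
#' extreme of any same-type neighbors.
#'
#' @param window a conditioned RESP `obs_window`.
#' @param min_period_s minimum breath period (default 1.5 s).
#' @return list with `peaks`, `troughs` (sample indices) and `times_peaks`,
#'   `times_troughs` (seconds).
#' @export
detect_breath_extrema <- function(window, min_period_s = 1.5) {
  stopifnot(inherits(window, "obs_window"))
  x <- window$samples
  fs <- window$fs
  if (window$flags$flatline || sd(x) == 0) {
    return(list(peaks = integer(0), troughs = integer(0),
                times_peaks = numeric(0), times_troughs = numeric(0)))
  }
  k <- max(3L, round(0.5 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- 0
  find_ext <- function(v, sign) {
    v <- sign * v
    n <- length(v)
    idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    # amplitude gate: ignore ripples below 20% of the robust amplitude
    idx[v[idx] > 0.2 * quantile(abs(v), 0.95)]
  }
  pk <- find_ext(xs, 1); tr <- find_ext(xs, -1)
  dedup <- function(idx, v, sign) {
    if (length(idx) < 2) return(idx)
    gap <- round(min_period_s * fs)
    out <- idx[1]
    for (i in idx[-1]) {
      if (i - out[length(out)] < gap) {
        if (sign * v[i] > sign * v[out[length(out)]]) out[length(out)] <- i
      } else out <- c(out, i)
    }
    out
  }
  pk <- dedup(pk, xs, 1); tr <- dedup(tr, xs, -1)
  # enforce alternation on the merged timeline
  ev <- rbind(data.frame(i = pk, type = 1), data.frame(i = tr, type = -1))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  if (nrow(ev) > 1) {
    for (r in 2:nrow(ev)) {
      prev <- max(which(keep[1:(r - 1)]))
      if (ev$type[r] == ev$type[prev]) {
        better <- ev$type[r] * xs[ev$i[r]] > ev$type[prev] * xs[ev$i[prev]]
        if (better) keep[prev] <- FALSE else keep[r] <- FALSE
      }
    }
  }
  ev <- ev[keep, ]
  pk <- ev$i[ev$type == 1]; tr <- ev$i[ev$type == -1]
  list(peaks = pk, troughs = tr,
       times_peaks = (pk - 1) / fs, times_troughs = (tr - 1) / fs)
}

# slice per-beat segments (midpoint to midpoint), resample to a common
# length, z-normalize each
beat_segments <- function(x, peaks, fs, resample_n = 64) {
  np <- length(peaks)
  if (np < 2) return(list())
  mids <- round((peaks[-np] + peaks[-1]) / 2)
  half <- round(median(diff(peaks)) / 2)
  bounds_lo <- c(max(1L, peaks[1] - half), mids)
  bounds_hi <- c(mids, min(length(x), peaks[np] + half))
  lapply(seq_len(np), function(k) {
    seg <- x[bounds_lo[k]:bounds_hi[k]]
    if (length(seg) < 3) return(rep(0, resample_n))
    r <- approx(seq_along(seg), seg, n = resample_n)$y
    s <- sd(r)
    if (s > 0) (r - mean(r)) / s else r - mean(r)
  })
}

#' Adjacent-waveform DTW statistics
#'
#' Segments the window into per-beat (or per-breath) waveforms, resamples
#' each to a common length, z-normalizes, and computes DTW distances between
#' consecutive segments. With fewer than 3 segments the rhythm is
#' unassessable and the configured sentinel distance is returned for all
#' three statistics.
#'
#' @param window a conditioned `obs_window`.
#' @param peaks sample indices of R peaks / breath peaks.
#' @param sentinel distance returned when fewer than 3 segments exist
#'   (default 10, far above any observed adjacent-beat distance).
#' @param resample_n common segment length before DTW (default 64).
#' @return list with `mean`, `max`, `sd` of adjacent-segment DTW distances.
#' @export
adjacent_waveform_dtw_stats <- function(window, peaks, sentinel = 10,
                                        resample_n = 64) {
  segs <- beat_segments(window$samples, peaks, window$fs, resample_n)
  if (length(segs) < 3) {
    return(list(mean = sentinel, max = sentinel, sd = sentinel))
  }
  d <- vapply(seq_len(length(segs) - 1), function(k) {
    dtw_distance(segs[[k]], segs[[k + 1]]) / resample_n
  }, 0)
  list(mean = mean(d), max = max(d), sd = if (length(d) > 1) sd(d) else 0)
}

# Welch PSD: Hann-windowed overlapping segments averaged; returns freq (Hz)
# and power density (one-sided, arbitrary scale)
welch_psd <- function(x, fs, nseg = NULL) {
  n <- length(x)
  if (is.null(nseg)) nseg <- min(n, 512L)
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  acc <- numeric(floor(nseg / 2) + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / length(starts)
  freq <- (seq_along(psd) - 1) * fs / nseg
  list(freq = freq, psd = psd)
}

#' Spectral descriptors of a window
#'
#' Welch-style power spectral density; returns the in-band power fraction
#' (ECG 0.5--40 Hz, RESP 0.1--0.6 Hz, relative to total), spectral entropy in
#' nats, the dominant (non-DC) frequency, and the high-band power fraction
#' (above 20 Hz for ECG, above 1 Hz for RESP).
#'
#' @param window a conditioned `obs_window`.
#' @return list `inband_frac`, `entropy`, `domfreq_hz`, `high_frac`, `nbins`.
#' @export
spectral_features <- function(window) {
  stopifnot(inherits(window, "obs_window"))
  x <- window$samples
  fs <- window$fs
  if (sd(x) == 0) {
    return(list(inband_frac = 0, entropy = 0, domfreq_hz = 0, high_frac = 0,
                nbins = 0L))
  }
  w <- welch_psd(x, fs)
  tot <- sum(w$psd)
  band <- if (window$kind == "ECG") c(0.5, 40) else c(0.1, 0.6)
  hi_cut <- if (window$kind == "ECG") 20 else 1
  inband <- sum(w$psd[w$freq >= band[1] & w$freq <= band[2]]) / tot
  high <- sum(w$psd[w$freq > hi_cut]) / tot
  p <- w$psd / tot
  p <- p[p > 0]
  ent <- -sum(p * log(p))
  nz <- which(w$freq > 0)
  domf <- w$freq[nz][which.max(w$psd[nz])]
  list(inband_frac = inband, entropy = ent, domfreq_hz = domf,
       high_frac = high, nbins = length(w$psd))
}

#' Feature names per signal kind
#'
#' The fixed, ordered feature lists: 8 descriptors for ECG windows and 18 for
#' RESP windows.
#'
#' @param kind `"ECG"` or `"RESP"`.
#' @return character vector of feature names in serialization order.
#' @export
feature_names <- function(kind = c("ECG", "RESP")) {
  kind <- match.arg(kind)
  if (kind == "ECG") {
    c("skewness", "kurtosis", "dtw_mean", "dtw_max", "rate_deviation",
      "amp_ratio", "inband_frac", "high_frac")
  } else {
    c("skewness", "kurtosis", "dtw_mean", "dtw_max", "dtw_sd",
      "n_breaths", "period_mean", "period_sd", "period_cv",
      "amp_mean", "amp_sd", "amp_cv", "trough_asym", "zcr",
      "inband_frac", "high_frac", "entropy", "domfreq_hz")
  }
}

sentinel_features <- function(kind, sentinel = 10) {
  nm <- feature_names(kind)
  v <- setNames(rep(0, length(nm)), nm)
  v[grep("^dtw", nm)] <- sentinel
  if (kind == "ECG") v["rate_deviation"] <- sentinel
  v
}

#' ECG feature vector for one conditioned window
#'
#' The 8 fixed features: skewness, kurtosis, mean and max adjacent-beat DTW
#' distance, R-peak count deviation from the rate implied by the median RR
#' interval, peak-to-peak amplitude ratio over 1 s subwindows (max/median),
#' in-band (0.5--40 Hz) power fraction and above-20 Hz power fraction.
#' Flatline-flagged windows return the sentinel vector.
#'
#' @param window a conditioned ECG `obs_window`.
#' @param sentinel sentinel value for unassessable descriptors.
#' @return named numeric vector of length 8.
#' @export
ecg_feature_vector <- function(window, sentinel = 10) {
  stopifnot(inherits(window, "obs_window"), window$kind == "ECG")
  if (window$flags$flatline) return(sentinel_features("ECG", sentinel))
  x <- window$samples
  det <- detect_r_peaks(window)
  dtw <- adjacent_waveform_dtw_stats(window, det$peaks, sentinel)
  npk <- length(det$peaks)
  rate_dev <- sentinel
  if (npk >= 3) {
    med_rr <- median(diff(det$peaks)) / window$fs
    expected <- window$length_s / med_rr
    rate_dev <- abs(npk - expected) / expected
  }
  # peak-to-peak amplitude per 1 s subwindow
  ns <- round(window$fs)
  nsw <- floor(length(x) / ns)
  p2p <- vapply(seq_len(nsw), function(k) {
    seg <- x[((k - 1) * ns + 1):(k * ns)]
    diff(range(seg))
  }, 0)
  amp_ratio <- if (median(p2p) > 0) max(p2p) / median(p2p) else sentinel
  sp <- spectral_features(window)
  setNames(c(skewness(x), kurtosis(x), dtw$mean, dtw$max, rate_dev,
             amp_ratio, sp$inband_frac, sp$high_frac),
           feature_names("ECG"))
}

#' Respiration feature vector for one conditioned window
#'
#' The 18 fixed features: skewness, kurtosis, mean/max/SD adjacent-breath DTW
#' distance, breath count, breath-period mean/SD/CV, peak-to-trough amplitude
#' mean/SD/CV, trough asymmetry, zero-crossing rate, respiratory-band
#' (0.1--0.6 Hz) power fraction, above-1 Hz power fraction, spectral entropy
#' and dominant frequency. Flatline-flagged windows return the sentinel
#' vector.
#'
#' @param window a conditioned RESP `obs_window`.
#' @param sentinel sentinel value for unassessable descriptors.
#' @return named numeric vector of length 18.
#' @export
resp_feature_vector <- function(window, sentinel = 10) {
  stopifnot(inherits(window, "obs_window"), window$kind == "RESP")
  if (window$flags$flatline) return(sentinel_features("RESP", sentinel))
  x <- window$samples
  ext <- detect_breath_extrema(window)
  dtw <- adjacent_waveform_dtw_stats(window, ext$peaks, sentinel)
  npk <- length(ext$peaks)
  per_m <- per_sd <- per_cv <- 0
  if (npk >= 2) {
    per <- diff(ext$peaks) / window$fs
    per_m <- mean(per)
    per_sd <- if (length(per) > 1) sd(per) else 0
    per_cv <- if (per_m > 0) per_sd / per_m else 0
  }
  amp_m <- amp_sd <- amp_cv <- asym <- 0
  if (npk >= 1 && length(ext$troughs) >= 1) {
    pk_v <- x[ext$peaks]; tr_v <- x[ext$troughs]
    amps <- numeric(0)
    for (p in seq_along(ext$peaks)) {
      nxt <- ext$troughs[ext$troughs > ext$peaks[p]]
      if (length(nxt)) amps <- c(amps, x[ext$peaks[p]] - x[nxt[1]])
    }
    if (length(amps)) {
      amp_m <- mean(amps)
      amp_sd <- if (length(amps) > 1) sd(amps) else 0
      amp_cv <- if (amp_m > 0) amp_sd / amp_m else 0
    }
    denom <- mean(abs(pk_v)) + mean(abs(tr_v))
    asym <- if (denom > 0) abs(mean(pk_v) + mean(tr_v)) / denom else 0
  }
  zcr <- sum(diff(sign(x)) != 0) / window$length_s
  sp <- spectral_features(window)
  setNames(c(skewness(x), kurtosis(x), dtw$mean, dtw$max, dtw$sd,
             npk, per_m, per_sd, per_cv, amp_m, amp_sd, amp_cv, asym, zcr,
             sp$inband_frac, sp$high_frac, sp$entropy, sp$domfreq_hz),
           feature_names("RESP"))
}

#' Extract the feature matrix for a set of records
#'
#' Segments each record into observation windows, conditions each window
#' independently, and assembles the fixed-order feature matrix. One row per
#' window, keyed by `(record_id, start_s)`; the `flatline` column marks
#' windows that bypassed feature extraction (sentinel rows).
#'
#' @param records a list of `signal_record` objects of one kind.
#' @param stride_s window stride; defaults to the window length.
#' @param sentinel sentinel feature value.
#' @return a data frame: `record_id`, `start_s`, `flatline`, then the
#'   feature columns of [feature_names()].
#' @export
extract_features <- function(records, stride_s = NULL, sentinel = 10) {
  if (inherits(records, "signal_record")) records <- list(records)
  stopifnot(length(records) > 0)
  kind <- records[[1]]$kind
  rows <- list()
  for (rec in records) {
    stopifnot(rec$kind == kind)
    for (w in segment_windows(rec, stride_s)) {
      cw <- condition_window(w)
      fv <- if (kind == "ECG") ecg_feature_vector(cw, sentinel)
      else resp_feature_vector(cw, sentinel)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(record_id = rec$record_id, start_s = w$start_s,
                   flatline = cw$flags$flatline, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)))
    }
  }
  do.call(rbind, rows)
}

#' Numeric feature matrix from a feature data frame
#'
#' Selects the fixed-order feature columns of [feature_names()] and drops
#' the key/metadata columns, for scoring with [anomaly_score()].
#'
#' @param features_df data frame from [extract_features()].
#' @param kind `"ECG"` or `"RESP"`.
#' @return numeric matrix with one row per window.
#' @export
feature_matrix <- function(features_df, kind) {
  as.matrix(features_df[, feature_names(kind), drop = FALSE])
}
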