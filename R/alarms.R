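# Simple documented rule-based arrhythmia flaggers and the false-alarm
# audit: an alarm is false when its onset lies in poor-quality signal.

as_record_window <- function(record) {
  structure(list(record_id = record$record_id, start_s = 0,
                 length_s = record_duration_s(record), fs = record$fs,
                 kind = record$kind, samples = record$samples,
                 flags = list(flatline = sd(record$samples) < 1e-6,
                              saturated = FALSE)),
            class = "obs_window")
}

#' Detect arrhythmia alarm events in an ECG record
#'
#' Rule-based flaggers over the beat sequence: instantaneous heart rate below
#' `brady_bpm` (default 50) sustained for at least `sustain_s` (default 10 s)
#' raises bradycardia; above `tachy_bpm` (default 100) raises tachycardia; a
#' beat arriving before 0.8 x the local median RR interval raises APB when
#' its waveform is of normal width/amplitude and VPB when wide or
#' large-amplitude.
#'
#' @param record an ECG `signal_record`.
#' @param peaks optional R-peak sample indices; detected if missing.
#' @param brady_bpm,tachy_bpm rate thresholds (bpm).
#' @param sustain_s minimum sustained duration for rate alarms (s).
#' @param premature_frac RR fraction below which a beat is premature.
#' @return data frame `type`, `onset_s`, `duration_s` (possibly 0 rows).
#' @export
detect_alarms <- function(record, peaks = NULL, brady_bpm = 50,
                          tachy_bpm = 100, sustain_s = 10,
                          premature_frac = 0.8) {
  stopifnot(inherits(record, "signal_record"), record$kind == "ECG")
  if (is.null(peaks)) {
    w <- condition_window(as_record_window(record))
    peaks <- detect_r_peaks(w)$peaks
    x <- w$samples
  } else {
    x <- record$samples
  }
  empty <- data.frame(type = character(0), onset_s = numeric(0),
                      duration_s = numeric(0), stringsAsFactors = FALSE)
  if (length(peaks) < 3) return(empty)
  tb <- (peaks - 1) / record$fs
  rr <- diff(tb)
  hr <- 60 / rr
  ev <- list()
  rate_runs <- function(flag, type) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      t0 <- tb[starts[k]]
      t1 <- tb[ends[k] + 1]
      if (t1 - t0 >= sustain_s) {
        ev[[length(ev) + 1]] <<- data.frame(type = type, onset_s = t0,
                                            duration_s = t1 - t0,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  rate_runs(hr < brady_bpm, "bradycardia")
  rate_runs(hr > tachy_bpm, "tachycardia")

  # beat morphology for premature-beat typing
  half <- round(0.12 * record$fs)
  beat_amp <- vapply(peaks, function(p) {
    sel <- max(1, p - half):min(length(x), p + half)
    diff(range(x[sel]))
  }, 0)
  beat_width <- vapply(peaks, function(p) {
    sel <- max(1, p - half):min(length(x), p + half)
    sum(abs(x[sel]) > 0.5 * abs(x[p])) / record$fs
  }, 0)
  med_amp <- median(beat_amp)
  med_wid <- median(beat_width)
  for (i in seq_along(rr)) {
    lo <- max(1, i - 4); hi <- min(length(rr), i + 4)
    local_med <- median(rr[lo:hi])
    if (rr[i] < premature_frac * local_med) {
      b <- i + 1  # the premature beat ends interval i
      wide <- beat_width[b] > 1.6 * med_wid || beat_amp[b] > 1.4 * med_amp
      ev[[length(ev) + 1]] <- data.frame(
        type = if (wide) "VPB" else "APB", onset_s = tb[b],
        duration_s = rr[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  out[order(out$onset_s), , drop = FALSE]
}

#' Audit alarms against a quality track
#'
#' An alarm is counted false when its onset falls in a poor-quality interval
#' of the track: by default only unacceptable intervals count as poor; the
#' strict policy also counts acceptable ones. Alarms whose onset is not
#' covered by the track are reported separately as unauditable.
#'
#' @param alarms data frame from [detect_alarms()].
#' @param track a `quality_track`.
#' @param policy `"unacceptable"` (default) or `"strict"`.
#' @return list with `per_type` (data frame `type`, `count`, `false_count`,
#'   `false_proportion`), `n_unauditable`, and `policy`.
#' @export
false_alarm_audit <- function(alarms, track,
                              policy = c("unacceptable", "strict")) {
  policy <- match.arg(policy)
  poor <- if (policy == "strict") c("acceptable", "unacceptable") else "unacceptable"
  types <- c("bradycardia", "tachycardia", "APB", "VPB")
  grade_at <- function(t) {
    hit <- which(track$start_s <= t & t < track$end_s)
    if (length(hit)) track$grade[hit[1]] else NA_character_
  }
  g <- if (nrow(alarms)) vapply(alarms$onset_s, grade_at, "") else character(0)
  unaud <- sum(is.na(g))
  per <- lapply(types, function(ty) {
    sel <- which(alarms$type == ty & !is.na(g))
    cnt <- length(sel)
    fc <- sum(g[sel] %in% poor)
    data.frame(type = ty, count = cnt, false_count = fc,
               false_proportion = if (cnt > 0) fc / cnt else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(per_type = do.call(rbind, per), n_unauditable = unaud, policy = policy)
}
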