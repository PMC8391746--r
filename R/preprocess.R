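# Window conditioning: segmentation, zero-phase band-pass filtering, robust
# outlier clipping and per-window normalization. Windows are conditioned
# independently (no cross-window state) so streaming and batch runs agree.

#' Segment a record into fixed-length observation windows
#'
#' Cuts 10 s (ECG) or 30 s (RESP) windows. Non-overlapping by default
#' (stride = window length); a trailing partial window is dropped.
#'
#' @param record a `signal_record`.
#' @param stride_s stride between window starts (s); defaults to the window
#'   length.
#' @return a list of `obs_window` objects (raw samples, not yet conditioned);
#'   empty with a warning if the record is shorter than one window.
#' @export
segment_windows <- function(record, stride_s = NULL) {
  stopifnot(inherits(record, "signal_record"))
  len <- window_length_s(record$kind)
  if (is.null(stride_s)) stride_s <- len
  if (stride_s <= 0) stop_param("stride_s must be > 0")
  dur <- record_duration_s(record)
  if (dur < len - 1e-9) {
    warning(sprintf("record %s (%.1f s) shorter than one %g s window",
                    record$record_id, dur, len))
    return(list())
  }
  starts <- seq(0, dur - len + 1e-9, by = stride_s)
  lapply(starts, function(s) {
    i0 <- round(s * record$fs) + 1L
    i1 <- i0 + round(len * record$fs) - 1L
    structure(list(record_id = record$record_id, start_s = s, length_s = len,
                   fs = record$fs, kind = record$kind,
                   samples = record$samples[i0:i1],
                   flags = list(flatline = FALSE, saturated = FALSE)),
              class = "obs_window")
  })
}

butter_safe <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  if (any(!is.finite(c(flt$b, flt$a)))) stop_param("filter design failed")
  flt
}

#' Zero-phase band-pass filter for one window
#'
#' Butterworth filtering applied forward and backward (zero phase). The pass
#' band defaults to 0.5--40 Hz for ECG and 0.05--1 Hz for RESP. The band is
#' realized as a cascade of an order-2 high-pass and an order-4 low-pass,
#' which stays numerically well conditioned for the very low respiratory
#' corner frequency at short windows.
#'
#' @param window an `obs_window`.
#' @param band length-2 pass band in Hz; default per kind.
#' @return the window with filtered samples.
#' @export
bandpass <- function(window, band = NULL) {
  stopifnot(inherits(window, "obs_window"))
  if (is.null(band)) {
    band <- if (window$kind == "ECG") c(0.5, 40) else c(0.05, 1)
  }
  nyq <- window$fs / 2
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    stop_param("band [%g, %g] Hz infeasible at fs = %g Hz",
               band[1], band[2], window$fs)
  }
  x <- window$samples
  hp <- butter_safe(2, band[1] / nyq, "high")
  lp <- butter_safe(4, band[2] / nyq, "low")
  x <- signal::filtfilt(hp, x)
  x <- signal::filtfilt(lp, x)
  if (any(!is.finite(x))) stop_param("filtering produced non-finite samples")
  window$samples <- x
  window
}

#' Clip outliers to a robust bound
#'
#' Samples outside `median(x) +/- k * robust scale` are clipped to the
#' bound. The robust scale is the trimmed half-range
#' `(quantile(x, 0.995) - quantile(x, 0.005)) / 4`: unlike the MAD it does
#' not collapse on spike-like waveforms such as ECG, whose samples are
#' mostly baseline, so physiological peaks survive while gross impulse
#' artifacts are clipped. A constant window (zero scale) passes through
#' unchanged.
#'
#' @param window an `obs_window`.
#' @param k bound multiplier (> 0, default 5).
#' @return the window with clipped samples.
#' @export
clip_outliers <- function(window, k = 5) {
  stopifnot(inherits(window, "obs_window"))
  if (k <= 0) stop_param("k must be > 0")
  x <- window$samples
  m <- median(x)
  s <- diff(quantile(x, c(0.005, 0.995), names = FALSE)) / 4
  if (s > 0) {
    window$samples <- pmin(pmax(x, m - k * s), m + k * s)
  }
  window
}

#' Normalize a window to zero mean and unit variance
#'
#' If the per-window standard deviation falls below `tol` the window is
#' flagged `flatline` and the samples are only mean-centered; flagged windows
#' bypass feature extraction and are graded unacceptable downstream.
#'
#' @param window an `obs_window`.
#' @param tol flatline standard-deviation tolerance in pre-normalization
#'   units (default 1e-6).
#' @return the window, normalized or flagged.
#' @export
normalize_window <- function(window, tol = 1e-6) {
  stopifnot(inherits(window, "obs_window"))
  x <- window$samples - mean(window$samples)
  s <- sd(x)
  if (!is.finite(s) || s < tol) {
    window$flags$flatline <- TRUE
    window$samples <- x
  } else {
    window$samples <- x / s
  }
  window
}

#' Condition a window for feature extraction
#'
#' Fixed pipeline: band-pass filter, outlier clip, normalize. Each stage
#' preserves length and never introduces non-finite values.
#'
#' @param window a raw `obs_window` from [segment_windows()].
#' @param band optional filter band override.
#' @param k outlier-clip multiplier.
#' @param flatline_tol flatline tolerance passed to [normalize_window()].
#' @return the conditioned window.
#' @export
condition_window <- function(window, band = NULL, k = 5, flatline_tol = 1e-6) {
  # a raw flatline (dropout across the whole window) is flagged before
  # filtering so filter transients cannot mask it
  if (sd(window$samples) < flatline_tol) {
    window$samples <- window$samples - mean(window$samples)
    window$flags$flatline <- TRUE
    return(window)
  }
  w <- bandpass(window, band)
  w <- clip_outliers(w, k)
  normalize_window(w, flatline_tol)
}
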