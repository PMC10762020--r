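# R-peak detection: 8-40 Hz bandpass followed by the dual
# moving-average (two event-related moving averages) detector.

#' Detection configuration
#'
#' Parameters of the bandpass filter and the dual moving-average R-peak
#' detector. The 8-40 Hz band isolates QRS energy while rejecting
#' baseline wander and T waves; the first moving average (window
#' `w_qrs`) tracks QRS-scale energy and the second (`w_beat`) tracks
#' beat-scale energy, and candidate QRS blocks are regions where the
#' first exceeds the second plus an offset `beta * mean(rectified)`.
#'
#' @param band_low,band_high Bandpass corner frequencies in Hz
#'   (defaults 8 and 40).
#' @param w_qrs First moving-average window in ms (default 97,
#'   approximately one QRS duration).
#' @param w_beat Second moving-average window in ms (default 611,
#'   approximately one beat duration).
#' @param beta Dimensionless offset factor applied to the mean of the
#'   rectified signal (default 0.08).
#' @param refractory Minimum separation of accepted peaks in ms
#'   (default 200); of two closer peaks the larger is kept.
#' @param rectifier `"square"` (default) or `"abs"`: how the filtered
#'   signal is rectified before averaging.
#' @param order Butterworth filter order (default 3; applied forward
#'   and backward, so the effective order is doubled).
#' @return A `detection_config` list.
#' @export
detection_config <- function(band_low = 8, band_high = 40,
                             w_qrs = 97, w_beat = 611, beta = 0.08,
                             refractory = 200,
                             rectifier = c("square", "abs"),
                             order = 3) {
  rectifier <- match.arg(rectifier)
  for (v in list(band_low = band_low, band_high = band_high,
                 w_qrs = w_qrs, w_beat = w_beat, beta = beta,
                 refractory = refractory, order = order))
    if (!is_scalar_number(v)) stop_config("config values must be single numbers")
  if (band_low <= 0 || band_high <= band_low)
    stop_config("need 0 < band_low < band_high")
  if (w_qrs <= 0 || w_beat <= w_qrs)
    stop_config("need 0 < w_qrs < w_beat (ms)")
  if (beta < 0) stop_config("beta must be >= 0")
  if (refractory <= 0) stop_config("refractory must be > 0 (ms)")
  structure(list(band_low = band_low, band_high = band_high,
                 w_qrs = w_qrs, w_beat = w_beat, beta = beta,
                 refractory = refractory, rectifier = rectifier,
                 order = order),
            class = "detection_config")
}

#' Zero-phase bandpass filter for QRS isolation
#'
#' Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), so the output has no phase lag and peak
#' timing is not skewed. The DC component and respiratory-band baseline
#' wander fall far below the 8 Hz corner and are removed.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [detection_config()].
#' @return A filtered [ecg_record()] of the same length and rate.
#' @export
bandpass_filter <- function(rec, cfg = detection_config()) {
  if (!inherits(rec, "ecg_record")) stop_input("`rec` must be an ecg_record")
  nyq <- rec$fs / 2
  if (cfg$band_high >= nyq)
    stop_config(sprintf(
      "band_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
      cfg$band_high, nyq))
  bf <- signal::butter(cfg$order, c(cfg$band_low, cfg$band_high) / nyq,
                       type = "pass")
  y <- signal::filtfilt(bf, rec$samples - mean(rec$samples))
  ecg_record(y, fs = rec$fs, label = rec$label)
}

# Detector core, assuming `filt` is already bandpassed. Shared by
# detect_rpeaks() and estimate_rr() (which filters once for both
# detection and RMS extraction).
.detect_on_filtered <- function(filt, cfg) {
  x <- filt$samples
  fs <- filt$fs
  n_qrs <- max(1L, round(cfg$w_qrs / 1000 * fs))
  n_beat <- max(2L, round(cfg$w_beat / 1000 * fs))
  n_refr <- round(cfg$refractory / 1000 * fs)
  if (length(x) < max(n_beat, 2L * n_refr))
    stop_input(sprintf(
      "record too short for detection: %d samples, need >= %d",
      length(x), max(n_beat, 2L * n_refr)))
  r <- if (cfg$rectifier == "square") x^2 else abs(x)
  ma_qrs <- moving_mean(r, n_qrs)
  ma_beat <- moving_mean(r, n_beat)
  above <- ma_qrs > ma_beat + cfg$beta * mean(r)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= n_qrs
  idx <- integer(0)
  for (b in which(keep)) {
    seg <- starts[b]:ends[b]
    idx <- c(idx, seg[which.max(abs(x[seg]))])
  }
  # enforce the refractory period, keeping the larger of two close peaks
  if (length(idx) > 1L) {
    amp <- abs(x[idx])
    i <- 2L
    while (i <= length(idx)) {
      if (idx[i] - idx[i - 1L] < n_refr) {
        drop <- if (amp[i] >= amp[i - 1L]) i - 1L else i
        idx <- idx[-drop]; amp <- amp[-drop]
        i <- max(2L, i - 1L)
      } else i <- i + 1L
    }
  }
  rpeak_list(idx, fs = fs)
}

#' Detected R-peaks
#'
#' @param indices 1-based sample positions of the peaks, strictly
#'   increasing.
#' @param fs Sampling frequency (Hz) the indices refer to.
#' @return An `rpeak_list` with elements `indices`, `times` (seconds,
#'   `(indices - 1) / fs`), `rr_intervals` (successive differences,
#'   length `n - 1`) and `fs`.
#' @export
rpeak_list <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop_input("peak indices must be strictly increasing")
  times <- (indices - 1) / fs
  structure(list(indices = indices, times = times,
                 rr_intervals = diff(times), fs = fs),
            class = "rpeak_list")
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("<rpeak_list> %d peaks", length(x$indices)))
  if (length(x$indices) > 1L)
    cat(sprintf(", mean R-R %.3f s (HR %.1f /min)",
                mean(x$rr_intervals), 60 / mean(x$rr_intervals)))
  cat("\n")
  invisible(x)
}

#' @export
length.rpeak_list <- function(x) length(x$indices)

#' Detect R-peaks with the dual moving-average method
#'
#' Pipeline: (1) zero-phase 8-40 Hz bandpass; (2) rectify (squaring by
#' default); (3) moving mean over `w_qrs`; (4) moving mean over
#' `w_beat`; (5) blocks of interest where the QRS-scale average exceeds
#' the beat-scale average plus `beta * mean(rectified)`; (6) blocks
#' shorter than `w_qrs` rejected; (7) the R-peak is the sample of
#' maximum filtered magnitude within each block; (8) peaks closer than
#' the refractory period merged, keeping the larger. Blocks touching
#' the record boundaries are kept; beats whose QRS window is incomplete
#' are dropped later, at RMS extraction.
#'
#' The detector is invariant to positive rescaling and to DC offsets of
#' the input. An alternative detector can be substituted anywhere a
#' peak list is consumed by constructing one with [rpeak_list()].
#'
#' @param rec An [ecg_record()] (raw; filtering is applied internally).
#' @param cfg A [detection_config()].
#' @return An [rpeak_list()]; empty if no peaks qualify.
#' @export
detect_rpeaks <- function(rec, cfg = detection_config()) {
  .detect_on_filtered(bandpass_filter(rec, cfg), cfg)
}

#' Inter-beat (R-R) intervals
#'
#' @param peaks An [rpeak_list()] with at least two peaks.
#' @return Numeric vector of successive peak-time differences in
#'   seconds.
#' @export
rr_intervals <- function(peaks) {
  if (!inherits(peaks, "rpeak_list")) stop_input("`peaks` must be an rpeak_list")
  if (length(peaks$indices) < 2L)
    stop_input("need at least 2 peaks to form intervals")
  peaks$rr_intervals
}
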