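# Core estimator: per-beat QRS RMS -> sliding beat-domain power
# spectrum -> dominant in-band peak -> breaths per minute -> median
# smoothing.

#' Estimator configuration
#'
#' @param qrs_window Width in ms of the window centered on each R-peak
#'   over which the QRS root-mean-square amplitude is computed
#'   (default 80).
#' @param spectral_window Number of consecutive per-beat RMS values per
#'   spectral estimate (default 16). Larger windows resolve frequency
#'   better but respond more slowly to rate changes.
#' @param nfft Zero-padded transform length (default 512); the spectral
#'   grid is `k / nfft` cycles/beat, `k = 0 .. nfft/2`.
#' @param rr_band Two-element numeric, the anticipated respiratory-rate
#'   range in breaths/min searched for the dominant peak. Default
#'   `c(1.8, 18)` (0.03-0.3 Hz at 60 beats/min); studies spanning
#'   faster breathing use `c(5, 40)`.
#' @param median_window Number of RR determinations in the trailing
#'   median smoother (default 16).
#' @return An `estimator_config` list.
#' @export
estimator_config <- function(qrs_window = 80, spectral_window = 16,
                             nfft = 512, rr_band = c(1.8, 18),
                             median_window = 16) {
  if (!is_scalar_number(qrs_window) || qrs_window <= 0)
    stop_config("qrs_window must be a positive number (ms)")
  if (!is_scalar_number(spectral_window) || spectral_window < 4)
    stop_config("spectral_window must be >= 4 beats")
  if (!is_scalar_number(nfft) || nfft < spectral_window)
    stop_config("nfft must be >= spectral_window")
  if (!is.numeric(rr_band) || length(rr_band) != 2L ||
      rr_band[1] <= 0 || rr_band[2] <= rr_band[1])
    stop_config("rr_band must be c(rr_min, rr_max) with 0 < rr_min < rr_max")
  if (!is_scalar_number(median_window) || median_window < 1)
    stop_config("median_window must be >= 1")
  structure(list(qrs_window = qrs_window,
                 spectral_window = as.integer(spectral_window),
                 nfft = as.integer(nfft),
                 rr_band = as.numeric(rr_band),
                 median_window = as.integer(median_window)),
            class = "estimator_config")
}

#' Per-beat QRS RMS amplitudes
#'
#' For every detected peak whose full window
#' `[t - qrs_window/2, t + qrs_window/2]` lies inside the record, the
#' root-mean-square amplitude `sqrt(mean(samples^2))` over that window
#' is computed. Beats with incomplete windows (at the record edges) are
#' dropped, and the drop is reported via [message()]. The record passed
#' in should be the bandpass-filtered signal, so that baseline wander
#' does not leak into the amplitude estimate.
#'
#' @param rec The filtered [ecg_record()] the peaks were detected on.
#' @param peaks An [rpeak_list()].
#' @param cfg An [estimator_config()].
#' @return A `beat_rms_series` with elements `rms` (one value per
#'   retained beat), `beat_times` (s) and `intervals`
#'   (`diff(beat_times)`).
#' @export
extract_qrs_rms <- function(rec, peaks, cfg = estimator_config()) {
  if (!inherits(rec, "ecg_record")) stop_input("`rec` must be an ecg_record")
  if (!inherits(peaks, "rpeak_list")) stop_input("`peaks` must be an rpeak_list")
  half <- round(cfg$qrs_window / 1000 * rec$fs / 2)
  n <- length(rec$samples)
  ok <- peaks$indices - half >= 1L & peaks$indices + half <= n
  if (sum(ok) == 0L)
    stop_input("no beat has a complete QRS window inside the record")
  if (any(!ok))
    message(sprintf("dropped %d beat(s) with incomplete QRS windows",
                    sum(!ok)))
  idx <- peaks$indices[ok]
  rms <- vapply(idx, function(i) {
    w <- rec$samples[(i - half):(i + half)]
    sqrt(mean(w^2))
  }, numeric(1))
  structure(list(rms = rms, beat_times = peaks$times[ok],
                 intervals = diff(peaks$times[ok])),
            class = "beat_rms_series")
}

#' @export
print.beat_rms_series <- function(x, ...) {
  cat(sprintf("<beat_rms_series> %d beats, RMS %.4g-%.4g\n",
              length(x$rms), min(x$rms), max(x$rms)))
  invisible(x)
}

#' Beat-domain power spectrum of one RMS window
#'
#' The window mean is subtracted (otherwise the DC lobe of the short
#' rectangular window can dominate the low-frequency end of the
#' respiratory band), the series is zero-padded to `nfft` points, and
#' the power is the squared magnitude of the discrete Fourier transform
#' taken on the beat-index axis. Frequencies are therefore in cycles
#' per beat; the window's mean R-R interval is carried along for the
#' conversion to breaths per minute.
#'
#' @param rms_window Exactly `spectral_window` finite RMS values.
#' @param intervals The R-R intervals (s) within the window, used for
#'   `mean_interval`.
#' @param cfg An [estimator_config()].
#' @return A `spectrum_window` with `freqs` (cycles/beat, `k / nfft`
#'   for `k = 0 .. nfft/2`), `power` and `mean_interval` (s).
#' @export
window_spectrum <- function(rms_window, intervals, cfg = estimator_config()) {
  if (length(rms_window) != cfg$spectral_window)
    stop_input(sprintf("need exactly %d RMS values (got %d)",
                       cfg$spectral_window, length(rms_window)))
  if (!all(is.finite(rms_window))) stop_input("RMS values must be finite")
  x <- rms_window - mean(rms_window)
  xp <- c(x, rep(0, cfg$nfft - length(x)))
  sp <- stats::fft(xp)
  half <- cfg$nfft %/% 2L
  structure(list(freqs = (0:half) / cfg$nfft,
                 power = Mod(sp[1:(half + 1L)])^2,
                 mean_interval = mean(intervals)),
            class = "spectrum_window")
}

#' Dominant in-band spectral frequency
#'
#' The user band `rr_band` (breaths/min) is converted to cycles per
#' beat with the window's mean R-R interval
#' (`f_cyc = rr_bpm * mean_interval / 60`), clipped at the beat-domain
#' Nyquist limit of 0.5 cycles/beat, and the grid frequency of maximum
#' power within the converted band is returned. Ties break toward the
#' lowest frequency, so output is deterministic.
#'
#' @param spec A [window_spectrum()] result.
#' @param cfg An [estimator_config()].
#' @return Dominant frequency in cycles per beat.
#' @export
dominant_frequency <- function(spec, cfg = estimator_config()) {
  band <- cfg$rr_band * spec$mean_interval / 60
  band[2] <- min(band[2], 0.5)
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(sel) == 0L)
    abort_respecg(sprintf(
      "RR band [%g, %g] bpm excludes every grid frequency at mean interval %.3f s",
      cfg$rr_band[1], cfg$rr_band[2], spec$mean_interval),
      "respecg_estimation_error")
  spec$freqs[sel[which.max(spec$power[sel])]]
}

#' Convert a beat-domain frequency to breaths per minute
#'
#' A modulation at `f_peak` cycles/beat with beats every
#' `mean_interval` seconds runs at `f_peak / mean_interval` Hz, i.e.
#' `60 * f_peak / mean_interval` breaths per minute.
#'
#' @param f_peak Frequency in cycles per beat (>= 0).
#' @param mean_interval Mean R-R interval in seconds (> 0).
#' @return Rate in breaths per minute.
#' @export
rr_from_peak <- function(f_peak, mean_interval) {
  if (any(f_peak < 0)) stop_input("f_peak must be >= 0")
  if (any(mean_interval <= 0)) stop_input("mean_interval must be > 0")
  60 * f_peak / mean_interval
}

#' Trailing median smoother
#'
#' Output `i` is the median of the up-to-`median_window` raw values
#' ending at `i`; the window shrinks at the start of the series, so the
#' output has the length of the input and is causal (suitable for
#' streaming). Even-count medians are the mean of the two central
#' values.
#'
#' @param rr_raw Numeric vector of raw RR determinations (bpm).
#' @param cfg An [estimator_config()] (only `median_window` is used).
#' @return Smoothed vector, same length.
#' @export
median_smooth <- function(rr_raw, cfg = estimator_config()) {
  if (length(rr_raw) < 1L) stop_input("need at least one value")
  w <- cfg$median_window
  vapply(seq_along(rr_raw), function(i) {
    stats::median(rr_raw[max(1L, i - w + 1L):i])
  }, numeric(1))
}

#' Estimate respiratory rate from a single-lead ECG
#'
#' Full pipeline: zero-phase 8-40 Hz bandpass, dual moving-average
#' R-peak detection, per-beat QRS RMS in an 80 ms window, sliding
#' 16-beat power spectra (stepped one beat at a time, zero-padded to
#' 512 points), dominant in-band peak, conversion to breaths/min with
#' each window's mean R-R interval, and trailing 16-point median
#' smoothing. Each determination is timestamped at the last beat of
#' its spectral window, so the output is causal.
#'
#' If the upper band edge exceeds the beat-domain Nyquist rate (half
#' the beat rate) a warning reports the effective ceiling. Windows
#' whose converted band contains no grid frequency are skipped and
#' counted in a message.
#'
#' @param rec An [ecg_record()] (raw).
#' @param cfg An [estimator_config()].
#' @param det_cfg A [detection_config()].
#' @return An `rr_series` with `times` (s), `rr_raw` and `rr_smoothed`
#'   (bpm), plus the detected `peaks` and the configurations used.
#' @examples
#' truth <- generate_ecg(synthetic_config(duration = 60, seed = 1))
#' rr <- estimate_rr(truth$record, estimator_config(rr_band = c(5, 40)))
#' mean(rr$rr_smoothed)
#' @export
estimate_rr <- function(rec, cfg = estimator_config(),
                        det_cfg = detection_config()) {
  filt <- bandpass_filter(rec, det_cfg)
  peaks <- .detect_on_filtered(filt, det_cfg)
  W <- cfg$spectral_window
  if (length(peaks$indices) < W)
    stop_input(sprintf(
      "only %d beat(s) detected; the spectral window needs at least %d",
      length(peaks$indices), W))
  beats <- extract_qrs_rms(filt, peaks, cfg)
  nb <- length(beats$rms)
  if (nb < W)
    stop_input(sprintf(
      "only %d beat(s) retained after QRS windowing; need at least %d",
      nb, W))
  mean_rate <- 60 / mean(beats$intervals)
  if (cfg$rr_band[2] > mean_rate / 2)
    warning(sprintf(
      paste0("rr_band upper edge (%g bpm) exceeds the beat-domain Nyquist ",
             "limit (%.1f bpm at %.0f beats/min); the search is clipped there"),
      cfg$rr_band[2], mean_rate / 2, mean_rate), call. = FALSE)
  nwin <- nb - W + 1L
  times <- rr_raw <- numeric(nwin)
  keep <- logical(nwin)
  for (i in seq_len(nwin)) {
    j <- i:(i + W - 1L)
    sp <- window_spectrum(beats$rms[j], diff(beats$beat_times[j]), cfg)
    f <- tryCatch(dominant_frequency(sp, cfg),
                  respecg_estimation_error = function(e) NA_real_)
    if (is.na(f)) next
    keep[i] <- TRUE
    rr_raw[i] <- rr_from_peak(f, sp$mean_interval)
    times[i] <- beats$beat_times[i + W - 1L]
  }
  if (sum(keep) == 0L)
    stop_input("no spectral window yielded an in-band estimate")
  if (any(!keep))
    message(sprintf("skipped %d window(s) with no in-band grid frequency",
                    sum(!keep)))
  times <- times[keep]; rr_raw <- rr_raw[keep]
  structure(list(times = times, rr_raw = rr_raw,
                 rr_smoothed = median_smooth(rr_raw, cfg),
                 peaks = peaks, config = cfg, det_config = det_cfg),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d determinations over %.1f s; smoothed RR %.2f-%.2f bpm (mean %.2f)\n",
    length(x$times), diff(range(x$times)),
    min(x$rr_smoothed), max(x$rr_smoothed), mean(x$rr_smoothed)))
  invisible(x)
}

#' @export
as.data.frame.rr_series <- function(x, ...) {
  data.frame(time_s = x$times, rr_raw_bpm = x$rr_raw,
             rr_bpm = x$rr_smoothed)
}
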