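#' Single-lead ECG record
#'
#' Container for a uniformly sampled single-lead voltage series and its
#' sampling frequency. All readers and the synthetic generator return
#' this class; all downstream stages consume it.
#'
#' @param samples Numeric vector of voltages (mV, or raw ADC units when
#'   a reader was given `scale = 1`). Must be finite and of length >= 2.
#' @param fs Sampling frequency in Hz (> 0).
#' @param label Free-text channel name.
#' @return An object of class `ecg_record` with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 5 * (0:999) / 250), fs = 250)
#' ecg_duration(rec)
#' @export
ecg_record <- function(samples, fs, label = "ECG") {
  if (!is_scalar_number(fs) || fs <= 0)
    stop_config("`fs` must be a single positive number (Hz)")
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop_input("an ECG record needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop_input("ECG samples must all be finite")
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.2f s)\n",
              x$label, length(x$samples), x$fs, ecg_duration(x)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Duration of an ECG record in seconds
#'
#' @param rec An [ecg_record()].
#' @return Duration in seconds (`n / fs`).
#' @export
ecg_duration <- function(rec) length(rec$samples) / rec$fs

#' Time axis of an ECG record
#'
#' @param rec An [ecg_record()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
ecg_times <- function(rec) (seq_along(rec$samples) - 1) / rec$fs
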