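# Readers and writers: raw 16-bit binary, delimited text/CSV, WFDB
# format-16 records, and the estimator's CSV output.

.encodings <- c("int16-le", "int16-be", "uint16-le", "uint16-be")

#' Read a single-lead ECG from raw 16-bit binary
#'
#' Decodes a headerless stream of 2-byte words. The sampling frequency
#' and the encoding are not recorded in such files and must be supplied.
#'
#' @param path Path to the binary file.
#' @param fs Sampling frequency in Hz.
#' @param encoding One of `"int16-le"` (default), `"int16-be"`,
#'   `"uint16-le"`, `"uint16-be"`.
#' @param scale Multiplier converting counts to mV (default 1: samples
#'   are returned in raw ADC units).
#' @param label Channel name for the record.
#' @return An [ecg_record()].
#' @export
read_binary_ecg <- function(path, fs, encoding = "int16-le", scale = 1,
                            label = basename(path)) {
  encoding <- match.arg(encoding, .encodings)
  if (!is_scalar_number(fs) || fs <= 0)
    stop_config("`fs` must be a single positive number (Hz)")
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  nbytes <- file.size(path)
  if (nbytes == 0) stop_format(sprintf("empty binary file: %s", path))
  if (nbytes %% 2 != 0)
    stop_format(sprintf(
      "truncated 16-bit binary file (%d bytes is not a whole number of 2-byte words): %s",
      nbytes, path))
  endian <- if (grepl("-le$", encoding)) "little" else "big"
  signed <- grepl("^int16", encoding)
  con <- file(path, "rb")
  on.exit(close(con))
  raw16 <- readBin(con, what = "integer", n = nbytes / 2, size = 2L,
                   signed = TRUE, endian = endian)
  if (!signed) raw16 <- ifelse(raw16 < 0, raw16 + 65536, raw16)
  ecg_record(raw16 * scale, fs = fs, label = label)
}

#' Write an ECG record as raw 16-bit binary
#'
#' Inverse of [read_binary_ecg()]: samples are divided by `scale`,
#' rounded to the nearest count and written as 2-byte words. Values
#' outside the representable range are an error rather than silently
#' wrapped.
#'
#' @inheritParams read_binary_ecg
#' @param rec An [ecg_record()].
#' @return `path`, invisibly.
#' @export
write_binary_ecg <- function(rec, path, encoding = "int16-le", scale = 1) {
  encoding <- match.arg(encoding, .encodings)
  counts <- round(rec$samples / scale)
  signed <- grepl("^int16", encoding)
  rng <- if (signed) c(-32768, 32767) else c(0, 65535)
  if (any(counts < rng[1] | counts > rng[2]))
    stop_format(sprintf(
      "samples exceed the %s range after scaling; adjust `scale`", encoding))
  if (!signed) counts <- ifelse(counts > 32767, counts - 65536, counts)
  endian <- if (grepl("-le$", encoding)) "little" else "big"
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(counts), con, size = 2L, endian = endian)
  invisible(path)
}

#' Read a single-lead ECG from delimited text or CSV
#'
#' One sample per row. The delimiter (comma versus whitespace) is
#' detected from the first line, a non-numeric header row is skipped
#' automatically, and lines starting with `#` are ignored.
#'
#' @param path Path to the text file.
#' @param fs Sampling frequency in Hz.
#' @param column 1-based index of the column holding the voltages.
#' @param label Channel name for the record.
#' @return An [ecg_record()].
#' @export
read_text_ecg <- function(path, fs, column = 1L, label = basename(path)) {
  if (!is_scalar_number(fs) || fs <= 0)
    stop_config("`fs` must be a single positive number (Hz)")
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_format(sprintf("no data lines in %s", path))
  sep <- if (grepl(",", lines[1L])) "," else "[[:space:]]+"
  fields <- strsplit(trimws(lines), sep)
  ncol1 <- length(fields[[1L]])
  if (column < 1L || column > ncol1)
    abort_respecg(sprintf(
      "column %d requested but %s has %d column(s)", column, path, ncol1),
      "respecg_parse_error")
  cells <- vapply(fields, function(f) {
    if (length(f) < column) NA_character_ else f[[column]]
  }, character(1))
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals))
  # a single leading non-numeric row is a header
  if (length(bad) > 0L && bad[1L] == 1L) {
    vals <- vals[-1L]; lineno <- lineno[-1L]
    bad <- which(is.na(vals))
  }
  if (length(bad) > 0L)
    abort_respecg(sprintf(
      "non-numeric value %s at line %d of %s",
      dQuote(cells[bad[1L] + (length(cells) - length(vals))]),
      lineno[bad[1L]], path),
      "respecg_parse_error")
  ecg_record(vals, fs = fs, label = label)
}

#' Read a single-lead channel from a WFDB record (format 16)
#'
#' Minimal reader for the text `.hea` header plus 16-bit little-endian
#' `.dat` signal file layout. The header-declared sampling frequency,
#' gain and baseline take precedence over any user-supplied values.
#' Multiplexed multi-signal files are de-interleaved and a single
#' channel returned.
#'
#' @param record Path to the record (with or without the `.hea`
#'   extension).
#' @param channel 1-based signal number to extract.
#' @return An [ecg_record()] in mV.
#' @export
read_wfdb_ecg <- function(record, channel = 1L) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop_io(sprintf("header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  if (is.na(nsig) || nsig < 1L) stop_format("bad WFDB header line")
  if (channel < 1L || channel > nsig)
    stop_input(sprintf("record has %d signal(s); channel %d requested",
                       nsig, channel))
  sig <- strsplit(trimws(lines[1L + channel]), "[[:space:]]+")[[1L]]
  datfile <- sig[1L]
  fmt <- sub("x.*$", "", sig[2L])
  if (fmt != "16")
    stop_format(sprintf("only WFDB format 16 is supported (got %s)", fmt))
  gainfield <- if (length(sig) >= 3L) sig[3L] else "200"
  gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gainfield))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gainfield))
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield)) else 0
  datpath <- file.path(dirname(hea), datfile)
  if (!file.exists(datpath)) stop_io(sprintf("signal file not found: %s", datpath))
  nbytes <- file.size(datpath)
  if (nbytes %% 2 != 0) stop_format("truncated WFDB format-16 signal file")
  con <- file(datpath, "rb")
  on.exit(close(con))
  adu <- readBin(con, "integer", n = nbytes / 2, size = 2L,
                 signed = TRUE, endian = "little")
  # format-16 files interleave samples across the signals they hold
  nshared <- sum(vapply(seq_len(nsig), function(k) {
    strsplit(trimws(lines[1L + k]), "[[:space:]]+")[[1L]][1L] == datfile
  }, logical(1)))
  if (nshared > 1L) {
    offset <- match(channel, which(vapply(seq_len(nsig), function(k) {
      strsplit(trimws(lines[1L + k]), "[[:space:]]+")[[1L]][1L] == datfile
    }, logical(1))))
    adu <- adu[seq(offset, length(adu), by = nshared)]
  }
  ecg_record((adu - baseline) / gain, fs = fs,
             label = sprintf("%s ch%d", basename(record), channel))
}

# Fourier-domain resampling of a real series to n2 points: the
# spectrum is truncated (downsampling) or zero-padded (upsampling),
# with the Nyquist bin split or folded so real input stays real. Exact
# for band-limited content; ringing is confined to the record edges.
fourier_resample <- function(x, n2) {
  n1 <- length(x)
  if (n2 == n1) return(x)
  X <- stats::fft(x)
  Y <- rep(0 + 0i, n2)
  N <- min(n1, n2)
  half <- N %/% 2L
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  nneg <- N - half - 1L
  if (nneg > 0L)
    Y[(n2 - nneg + 1L):n2] <- X[(n1 - nneg + 1L):n1]
  if (N %% 2L == 0L) {
    if (n2 > n1) {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[n2 - half + 1L] <- X[half + 1L] / 2
    } else if (n2 < n1) {
      Y[half + 1L] <- X[half + 1L] + X[n1 - half + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n1
}

#' Resample an ECG record to a new rate
#'
#' Band-limited Fourier resampling (spectrum truncation or
#' zero-padding, not linear interpolation) so that R-wave amplitudes —
#' the measurand of the downstream RR estimator — are preserved. A pure
#' tone below both Nyquist rates keeps its amplitude within 1% and its
#' peak timing within one target-rate sample; ringing from the implicit
#' periodic extension is confined to the record edges.
#'
#' @param rec An [ecg_record()].
#' @param target_fs Target sampling frequency in Hz.
#' @return An [ecg_record()] at `target_fs` with the same duration to
#'   within one target-rate sample.
#' @export
resample_ecg <- function(rec, target_fs) {
  if (!is_scalar_number(target_fs) || target_fs <= 0)
    stop_config("`target_fs` must be a single positive number (Hz)")
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  x <- rec$samples
  n1 <- length(x)
  n_target <- round(n1 * target_fs / rec$fs)
  # pad to a 2-3-5-smooth length so the FFT stays O(n log n); hold the
  # last value to limit the wrap-around discontinuity
  npad <- stats::nextn(n1, c(2L, 3L, 5L))
  if (npad > n1) x <- c(x, rep(x[n1], npad - n1))
  y <- fourier_resample(x, round(npad * target_fs / rec$fs))
  ecg_record(y[seq_len(n_target)], fs = target_fs, label = rec$label)
}

#' Write an RR series to CSV
#'
#' Two columns, `time_s` and `rr_bpm` (the smoothed estimates), one row
#' per RR determination, with a header row.
#'
#' @param rr An [rr_series] as returned by [estimate_rr()], or a data
#'   frame with columns `time_s` and `rr_bpm`.
#' @param path Output path.
#' @param raw If `TRUE`, write the unsmoothed estimates instead.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path, raw = FALSE) {
  df <- if (inherits(rr, "rr_series")) {
    data.frame(time_s = rr$times,
               rr_bpm = if (raw) rr$rr_raw else rr$rr_smoothed)
  } else {
    if (!all(c("time_s", "rr_bpm") %in% names(rr)))
      stop_input("`rr` needs columns time_s and rr_bpm")
    rr[, c("time_s", "rr_bpm")]
  }
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read an RR series CSV
#'
#' Reads the two-column `time_s`/`rr_bpm` layout written by
#' [write_rr_csv()] (also the format for external reference series).
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV.
#' @return A data frame with columns `time_s` and `rr_bpm`.
#' @export
read_rr_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) abort_respecg(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)),
      "respecg_parse_error"))
  if (ncol(df) < 2L)
    abort_respecg(sprintf("%s needs >= 2 columns (time_s, rr_bpm)", path),
                  "respecg_parse_error")
  names(df)[1:2] <- c("time_s", "rr_bpm")
  for (col in c("time_s", "rr_bpm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      abort_respecg(sprintf(
        "non-numeric %s value at data line %d of %s", col, bad[1L], path),
        "respecg_parse_error")
    df[[col]] <- v
  }
  df[stats::complete.cases(df[, 1:2]), 1:2]
}
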