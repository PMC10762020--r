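test_that("16-bit binary decoding honours encoding and scale", {
  f <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.raw(c(0x00, 0x01, 0x00, 0x02)), f)  # int16-le: 256, 512
  rec <- read_binary_ecg(f, fs = 100)
  expect_equal(rec$samples, c(256, 512))
  expect_equal(rec$fs, 100)
  rec2 <- read_binary_ecg(f, fs = 100, scale = 0.5)
  expect_equal(rec2$samples, c(128, 256))
  # same bytes as big-endian: 0x0001 -> 1, 0x0002 -> 2
  expect_equal(read_binary_ecg(f, fs = 100, encoding = "int16-be")$samples,
               c(1, 2))
})

test_that("degenerate binary files are rejected with format errors", {
  f <- withr::local_tempfile(fileext = ".bin")
  file.create(f)
  expect_error(read_binary_ecg(f, fs = 100), class = "respecg_format_error")
  writeBin(as.raw(c(0x00, 0x01, 0x02)), f)  # odd byte count
  expect_error(read_binary_ecg(f, fs = 100), class = "respecg_format_error")
  writeBin(as.raw(c(0x00, 0x01, 0x00, 0x02)), f)
  expect_error(read_binary_ecg(f, fs = -1), class = "respecg_config_error")
})

test_that("binary write-read round trip is bit-exact for all encodings", {
  x <- round(3000 * sin(2 * pi * 7 * (0:499) / 250))
  rec <- ecg_record(x, fs = 250)
  for (enc in c("int16-le", "int16-be", "uint16-le", "uint16-be")) {
    xx <- if (grepl("^uint", enc)) rec$samples - min(rec$samples) else rec$samples
    r0 <- ecg_record(xx, fs = 250)
    f <- withr::local_tempfile(fileext = ".bin")
    write_binary_ecg(r0, f, encoding = enc)
    expect_identical(read_binary_ecg(f, fs = 250, encoding = enc)$samples,
                     r0$samples, info = enc)
  }
})

test_that("text/CSV reading handles headers, columns and bad cells", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0", "2.0", "3.0"), f)
  rec <- read_text_ecg(f, fs = 100)
  expect_equal(rec$samples, c(1, 2, 3))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ecg_mv", "0,0.1", "1,0.2", "2,0.3"), g)
  expect_equal(read_text_ecg(g, fs = 100, column = 2)$samples,
               c(0.1, 0.2, 0.3))
  expect_error(read_text_ecg(g, fs = 100, column = 5),
               class = "respecg_parse_error")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2", "oops", "0.4"), h)
  err <- tryCatch(read_text_ecg(h, fs = 100), error = identity)
  expect_s3_class(err, "respecg_parse_error")
  expect_match(conditionMessage(err), "line 3")
})

test_that("resampling preserves duration and band-limited amplitude", {
  fs <- 256; dur <- 10
  tone <- sin(2 * pi * 5 * (0:(fs * dur - 1)) / fs)
  rec <- resample_ecg(ecg_record(tone, fs = fs), 1000)
  expect_equal(rec$fs, 1000)
  expect_equal(length(rec$samples), dur * 1000, tolerance = 1e-9)
  # interior peak-to-peak amplitude within 1% (edges carry FIR transients)
  core <- rec$samples[500:(length(rec$samples) - 500)]
  expect_equal(max(core) - min(core), 2, tolerance = 0.01)

  same <- ecg_record(tone, fs = fs)
  expect_identical(resample_ecg(same, fs)$samples, tone)
  expect_error(resample_ecg(same, 0), class = "respecg_config_error")

  # down-then-up round trip keeps the tone within 2%
  back <- resample_ecg(resample_ecg(ecg_record(tone, fs = fs), 100), fs)
  corei <- 400:(length(back$samples) - 400)
  expect_equal(max(back$samples[corei]) - min(back$samples[corei]), 2,
               tolerance = 0.02)
})

test_that("resampled tone keeps peak timing within one target sample", {
  fs <- 250
  t <- (0:(fs * 4 - 1)) / fs
  tone <- cos(2 * pi * 2 * (t - 1.0))  # peak exactly at t = 1 s
  rec <- resample_ecg(ecg_record(tone, fs = fs), 1000)
  tt <- ecg_times(rec)
  core <- tt > 0.6 & tt < 1.4
  tpeak <- tt[core][which.max(rec$samples[core])]
  expect_lt(abs(tpeak - 1.0), 1 / 1000 + 1e-9)
})

test_that("RR CSV output round-trips and degenerate series work", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(data.frame(time_s = numeric(0), rr_bpm = numeric(0)), f)
  expect_equal(length(readLines(f)), 1L)  # header only

  df <- data.frame(time_s = c(1.5, 2.5, 3.5),
                   rr_bpm = c(11.123456789, 12.5, 13.000001))
  write_rr_csv(df, f)
  expect_equal(length(readLines(f)), 4L)
  back <- read_rr_csv(f)
  expect_equal(back$rr_bpm, df$rr_bpm, tolerance = 1e-6)
  expect_equal(back$time_s, df$time_s, tolerance = 1e-6)
})

test_that("WFDB format-16 records are read with header gain and fs", {
  dir <- withr::local_tempdir()
  adu <- as.integer(round(200 * sin(2 * pi * 3 * (0:999) / 500)) + 10)
  writeBin(adu, file.path(dir, "rec01.dat"), size = 2L, endian = "little")
  writeLines(c("rec01 1 500 1000",
               "rec01.dat 16 200(10)/mV 16 0 0 0 0 ECG"),
             file.path(dir, "rec01.hea"))
  rec <- read_wfdb_ecg(file.path(dir, "rec01"))
  expect_equal(rec$fs, 500)
  expect_equal(rec$samples, (adu - 10) / 200)
  expect_error(read_wfdb_ecg(file.path(dir, "rec01"), channel = 2),
               class = "respecg_input_error")
})
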