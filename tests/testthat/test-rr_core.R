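test_that("QRS RMS is sqrt(mean(x^2)) over the centered window", {
  # constant record: RMS equals |a| regardless of sign
  rec <- ecg_record(rep(-2.5, 1000), fs = 1000)
  pk <- rpeak_list(c(200L, 500L, 800L), fs = 1000)
  out <- extract_qrs_rms(rec, pk)
  expect_equal(out$rms, rep(2.5, 3))

  # 3-sample window [3, -4, 3] with a 2 ms window at 1 kHz
  x <- rep(0, 50); x[24:26] <- c(3, -4, 3)
  rec2 <- ecg_record(x, fs = 1000)
  out2 <- extract_qrs_rms(rec2, rpeak_list(25L, fs = 1000),
                          estimator_config(qrs_window = 2))
  expect_equal(out2$rms, sqrt((9 + 16 + 9) / 3))
})

test_that("beats with incomplete QRS windows are dropped, not padded", {
  rec <- ecg_record(rep(1, 1000), fs = 1000)  # 80 ms window needs 40 ms margin
  pk <- rpeak_list(c(10L, 500L, 995L), fs = 1000)
  expect_message(out <- extract_qrs_rms(rec, pk), "dropped 2")
  expect_equal(out$beat_times, 499 / 1000)
  pk_all_edge <- rpeak_list(c(5L, 998L), fs = 1000)
  expect_error(suppressMessages(extract_qrs_rms(rec, pk_all_edge)),
               class = "respecg_input_error")
})

test_that("per-beat RMS tracks the generator's modulation linearly", {
  truth <- generate_ecg(synthetic_config(duration = 90, noise_sd = 0,
                                         wander_amp = 0, hr_jitter_sd = 0,
                                         mod_depth = 0.1, seed = 6))
  det <- detection_config()
  filt <- bandpass_filter(truth$record, det)
  peaks <- detect_rpeaks(truth$record, det)
  out <- extract_qrs_rms(filt, peaks)
  # match retained beats to true modulation factors
  scale <- truth$modulation[vapply(out$beat_times, function(t)
    which.min(abs(truth$beat_times - t)), integer(1))]
  ratio <- out$rms / scale
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.01)
})

test_that("window spectrum is the zero-padded DFT of the detrended window", {
  cfg <- estimator_config()
  n <- 0:15

  const <- window_spectrum(rep(4.2, 16), rep(1, 15), cfg)
  expect_lt(max(const$power), 1e-18)
  expect_equal(const$freqs[1], 0)
  expect_equal(const$freqs[length(const$freqs)], 0.5)

  ongrid <- window_spectrum(sin(2 * pi * 0.25 * n), rep(1, 15), cfg)
  expect_equal(ongrid$freqs[which.max(ongrid$power)], 0.25)  # bin 128/512

  off <- window_spectrum(sin(2 * pi * 0.2 * n), rep(1, 15), cfg)
  fhat <- off$freqs[which.max(off$power)]
  expect_lt(abs(fhat - 0.2), 1 / 512 + 1e-12)
  # cross-check against the brute-force DFT oracle on the same grid
  expect_equal(fhat, bf_dominant(sin(2 * pi * 0.2 * n), off$freqs))

  expect_error(window_spectrum(1:8, rep(1, 7), cfg),
               class = "respecg_input_error")
})

test_that("dominant frequency searches the converted band, lowest-tie", {
  cfg <- estimator_config(rr_band = c(5, 40))
  freqs <- (0:256) / 512
  mkspec <- function(power, mi = 1.0)
    structure(list(freqs = freqs, power = power, mean_interval = mi),
              class = "spectrum_window")

  # band 5-40 bpm at interval 1 s -> 0.0833-0.6667 cycles/beat, clipped at 0.5
  p <- rep(0, 257); p[200] <- 5  # freq 199/512 = 0.3887, inside band
  expect_equal(dominant_frequency(mkspec(p), cfg), 199 / 512)
  # energy below the band edge must be ignored
  p2 <- p; p2[20] <- 100  # 19/512 = 0.037 < 0.0833
  expect_equal(dominant_frequency(mkspec(p2), cfg), 199 / 512)
  # ties break toward the lowest frequency
  p3 <- rep(0, 257); p3[c(100, 150)] <- 7
  expect_equal(dominant_frequency(mkspec(p3), cfg), 99 / 512)
  # a band excluding every grid point is an estimation error
  tight <- estimator_config(rr_band = c(30, 31))
  expect_error(dominant_frequency(mkspec(p, mi = 0.001), tight),
               class = "respecg_estimation_error")
})

test_that("beat-domain frequency converts to bpm via the mean interval", {
  expect_equal(rr_from_peak(0.2, 1.0), 12)
  expect_equal(rr_from_peak(0.2, 0.5), 24)
  expect_equal(rr_from_peak(0.03, 1.0), 1.8)  # band edge: 0.03 Hz at 60 beats/min
  expect_error(rr_from_peak(0.2, 0), class = "respecg_input_error")
  expect_error(rr_from_peak(-0.1, 1), class = "respecg_input_error")
})

test_that("median smoothing is trailing, shrinking and robust", {
  cfg <- estimator_config(median_window = 16)
  expect_equal(median_smooth(rep(12, 40), cfg), rep(12, 40))

  spiky <- c(rep(10, 8), 30, rep(10, 8))
  expect_false(any(median_smooth(spiky, cfg) == 30))

  steps <- c(rep(10, 8), rep(12, 8))
  sm <- median_smooth(steps, cfg)
  expect_equal(sm[16], 11.0)  # even-count median of 8x10, 8x12
  expect_equal(sm[1], 10)     # window shrinks at the start
  expect_length(sm, 16L)
  # oracle: every output is the median of its trailing window
  raw <- sin(1:50) * 3 + 12
  sm2 <- median_smooth(raw, estimator_config(median_window = 5))
  for (i in c(1, 3, 7, 50))
    expect_equal(sm2[i], median(raw[max(1, i - 4):i]))
})

test_that("full estimator recovers a steady 12 bpm ventilation rate", {
  truth <- steady_truth(seed = 11, duration = 90)
  rr <- estimate_quiet(truth$record)
  expect_equal(mean(rr$rr_smoothed), 12, tolerance = 0.5 / 12)
  expect_true(all(diff(rr$times) > 0))
  # smoothed values never exceed the raw values in their window
  w <- rr$config$median_window
  for (i in seq_along(rr$rr_smoothed)) {
    win <- rr$rr_raw[max(1, i - w + 1):i]
    expect_gte(rr$rr_smoothed[i], min(win))
    expect_lte(rr$rr_smoothed[i], max(win))
  }
})

test_that("estimates are clipped to the configured band", {
  truth <- steady_truth(seed = 12, duration = 90)
  rr <- estimate_quiet(truth$record, estimator_config(rr_band = c(5, 10)))
  expect_true(all(rr$rr_smoothed <= 10))
  expect_true(all(rr$rr_smoothed >= 5))
})

test_that("the estimator is invariant to positive rescaling", {
  truth <- steady_truth(seed = 13, duration = 90)
  rr1 <- estimate_quiet(truth$record)
  scaled <- ecg_record(3.7 * truth$record$samples, fs = truth$record$fs)
  rr2 <- estimate_quiet(scaled)
  expect_equal(rr1$rr_smoothed, rr2$rr_smoothed)
  expect_equal(rr1$times, rr2$times)
})

test_that("spectral peak finder agrees with the brute-force oracle", {
  cfg <- estimator_config(rr_band = c(5, 40))
  n <- 0:15
  # oracle equivalence holds at every frequency and phase
  for (f0 in c(0.10, 0.18, 0.25, 0.33, 0.41)) for (ph in c(0, 0.3, 1.1)) {
    x <- 1 + 0.1 * sin(2 * pi * f0 * n + ph)
    sp <- window_spectrum(x, rep(1, 15), cfg)
    fhat <- dominant_frequency(sp, cfg)
    sel <- sp$freqs >= 5 / 60 & sp$freqs <= 0.5
    expect_equal(fhat, bf_dominant(x, sp$freqs[sel]),
                 info = sprintf("f0 %g phase %g", f0, ph))
  }
  # in the mid-band, where the 16-sample window's mirror-image leakage
  # is negligible, the peak recovers f0 within one grid spacing (at the
  # band edges the leakage bias can reach ~2 bins; see the vignette)
  for (f0 in c(0.18, 0.20, 0.25, 0.33)) {
    x <- 1 + 0.1 * sin(2 * pi * f0 * n)
    sp <- window_spectrum(x, rep(1, 15), cfg)
    expect_lt(abs(dominant_frequency(sp, cfg) - f0), 1 / 512 + 1e-12)
  }
})

test_that("settling delay after a step grows with the spectral window", {
  prot <- stepped_protocol(c(10, 20), c(120, 120))
  truth <- generate_ecg(synthetic_config(duration = 240, rr = prot,
                                         seed = 14))
  delay <- vapply(c(8, 16, 32, 64), function(W) {
    rr <- estimate_quiet(truth$record,
                         estimator_config(rr_band = c(5, 40),
                                          spectral_window = W))
    post <- rr$times > 120
    settled <- post & rr$rr_smoothed >= 19  # within 10% of the step size
    if (!any(settled)) return(Inf)
    min(rr$times[settled]) - 120
  }, numeric(1))
  expect_true(all(diff(delay) >= 0))
})

test_that("true RR is recovered across the rate grid on clean input", {
  for (hr in c(60, 90)) for (rr0 in c(6, 10, 12, 18, 30)) {
    if (rr0 >= hr / 2) next  # beat-domain Nyquist limit
    truth <- generate_ecg(synthetic_config(duration = 90, hr = hr, rr = rr0,
                                           noise_sd = 0, wander_amp = 0,
                                           seed = 15))
    rr <- estimate_quiet(truth$record)
    expect_lt(mean(abs(rr$rr_smoothed - rr0)), 0.5,
              label = sprintf("MAE at HR %d, RR %g", hr, rr0))
  }
})

test_that("too few beats is a clear input error", {
  truth <- steady_truth(seed = 16, duration = 12)
  expect_error(estimate_quiet(truth$record), class = "respecg_input_error")
})
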