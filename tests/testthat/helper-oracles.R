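# Independent oracles used across the suite.

# Brute-force DFT power at one frequency (cycles per sample/beat).
bf_dft_power <- function(x, f) {
  n <- seq_along(x) - 1
  Mod(sum(x * exp(-2i * pi * f * n)))^2
}

# Exhaustive grid argmax of the detrended brute-force spectrum over
# freqs (cycles/beat).
bf_dominant <- function(x, freqs) {
  x <- x - mean(x)
  p <- vapply(freqs, function(f) bf_dft_power(x, f), numeric(1))
  freqs[which.max(p)]
}

# Closed-form ordinary least squares of y on x (slope, intercept, R^2).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  list(slope = b, intercept = a,
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

# Exact two-sided rank-sum p-value by enumerating every assignment of
# the pooled ranks to the first group (tie-free data only).
ranksum_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  wobs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  wall <- apply(combos, 2, function(i) sum(r[i]))
  mu <- length(x) * (length(pooled) + 1) / 2
  mean(abs(wall - mu) >= abs(wobs - mu) - 1e-9)
}

# Steady synthetic record emulating a mechanically ventilated subject.
steady_truth <- function(seed, duration = 120, rr = 12, hr = 60,
                         noise_sd = 0.02, ...) {
  generate_ecg(synthetic_config(duration = duration, hr = hr, rr = rr,
                                noise_sd = noise_sd, seed = seed, ...))
}

study_cfg <- function(...) estimator_config(rr_band = c(5, 40), ...)

estimate_quiet <- function(rec, cfg = study_cfg(), ...) {
  suppressWarnings(suppressMessages(estimate_rr(rec, cfg, ...)))
}
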