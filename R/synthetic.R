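# Synthetic single-lead ECG with known beat times and known
# respiratory amplitude modulation, so every pipeline stage can be
# validated against ground truth without external recordings.

#' Piecewise-constant respiratory-rate protocol
#'
#' Builds the stepped "ventilator" style protocol: the rate holds each
#' level for its segment duration, in order. A classic validation
#' pattern is small steps around a nominal setting, e.g.
#' `stepped_protocol(c(11, 10, 12, 10, 11), 120)`.
#'
#' @param levels Rates in breaths/min, all > 0.
#' @param segment_s Duration of each segment in seconds (recycled to
#'   the number of levels).
#' @return An `rr_protocol`: a function of time (s) returning bpm, with
#'   attributes `duration` (s) and `levels`.
#' @export
stepped_protocol <- function(levels, segment_s) {
  if (length(levels) == 0L) stop_config("`levels` must be non-empty")
  if (any(levels <= 0)) stop_config("all protocol levels must be > 0 bpm")
  segment_s <- rep_len(segment_s, length(levels))
  if (any(segment_s <= 0)) stop_config("segment durations must be > 0 s")
  edges <- c(0, cumsum(segment_s))
  f <- function(t) {
    i <- findInterval(pmin(pmax(t, 0), edges[length(edges)] - 1e-9), edges,
                      rightmost.closed = TRUE)
    levels[pmax(1L, pmin(i, length(levels)))]
  }
  structure(f, duration = sum(segment_s), levels = levels,
            edges = edges, class = c("rr_protocol", "function"))
}

#' Smoothly varying rate protocol
#'
#' Interpolates (monotone cubic) through `(times, values)` anchors;
#' used to emulate spontaneous breathing whose rate drifts slowly, and
#' equally usable for a heart-rate trajectory.
#'
#' @param times Anchor times in seconds, increasing, starting at 0.
#' @param values Rates (bpm) at the anchors, all > 0.
#' @return An `rr_protocol` function of time with a `duration`
#'   attribute.
#' @export
smooth_protocol <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2L)
    stop_config("need matching times/values vectors of length >= 2")
  if (any(values <= 0)) stop_config("rates must be > 0 bpm")
  if (is.unsorted(times, strictly = TRUE))
    stop_config("anchor times must be strictly increasing")
  f <- stats::splinefun(times, values, method = "monoH.FC")
  g <- function(t) f(pmin(pmax(t, times[1L]), times[length(times)]))
  structure(g, duration = times[length(times)], levels = range(values),
            class = c("rr_protocol", "function"))
}

#' Synthetic-ECG configuration
#'
#' Defaults emulate an anesthetized, mechanically ventilated subject: a
#' steady 60 beats/min heart rate with little beat-to-beat jitter, a
#' fixed ventilator rate of 12 breaths/min, 10% amplitude modulation of
#' the beat template, mild baseline wander and additive noise at 2% of
#' the 1 mV R amplitude.
#'
#' @param fs Sampling frequency in Hz (>= 250; default 1000, the
#'   analysis rate used throughout).
#' @param duration Record length in seconds.
#' @param hr Heart rate in beats/min: a constant or a function of time
#'   (e.g. a [smooth_protocol()]).
#' @param hr_jitter_sd Per-beat interval jitter SD in seconds
#'   (default 0.01).
#' @param rr Respiratory-rate protocol: a constant (bpm), or an
#'   `rr_protocol` from [stepped_protocol()] / [smooth_protocol()], or
#'   any function of time returning bpm.
#' @param mod_depth Fractional amplitude-modulation depth, `0 <= m < 1`
#'   (default 0.1): each beat is scaled by
#'   `1 + mod_depth * sin(phase(t))` where the phase advances at the
#'   instantaneous respiratory rate.
#' @param wander_amp,wander_freq Baseline-wander sinusoid amplitude
#'   (mV) and frequency (Hz); defaults 0.05 mV at 0.25 Hz.
#' @param noise_sd Additive white Gaussian noise SD in mV
#'   (default 0.02).
#' @param st_shift ST-segment offset in mV added to the beat template
#'   (default 0), emulating the morphology change of acute ischemia.
#' @param t_amp T-wave amplitude in mV (default 0.3); alter together
#'   with `st_shift` for infarction-like morphology.
#' @param r_amp R-wave amplitude in mV (default 1).
#' @param seed Integer seed; when set, output is bit-exactly
#'   reproducible. Randomness is consumed in a fixed order: first the
#'   per-beat interval jitter (one draw per beat, in beat order), then
#'   the noise vector.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 1000, duration = 120, hr = 60,
                             hr_jitter_sd = 0.01, rr = 12,
                             mod_depth = 0.1, wander_amp = 0.05,
                             wander_freq = 0.25, noise_sd = 0.02,
                             st_shift = 0, t_amp = 0.3, r_amp = 1,
                             seed = NULL) {
  if (!is_scalar_number(fs) || fs < 250)
    stop_config("fs must be >= 250 Hz")
  if (!is_scalar_number(duration) || duration <= 0)
    stop_config("duration must be > 0 s")
  if (!is.function(hr) && (!is_scalar_number(hr) || hr <= 0))
    stop_config("hr must be a positive number or a function of time")
  if (!is_scalar_number(mod_depth) || mod_depth < 0 || mod_depth >= 1)
    stop_config("mod_depth must satisfy 0 <= m < 1")
  if (!is_scalar_number(hr_jitter_sd) || hr_jitter_sd < 0)
    stop_config("hr_jitter_sd must be >= 0 s")
  if (!is.function(rr) && (!is_scalar_number(rr) || rr <= 0))
    stop_config("rr must be a positive rate or a protocol function")
  if (!is.null(seed) && !is_scalar_number(seed))
    stop_config("seed must be a single integer or NULL")
  structure(list(fs = fs, duration = duration, hr = hr,
                 hr_jitter_sd = hr_jitter_sd, rr = rr,
                 mod_depth = mod_depth, wander_amp = wander_amp,
                 wander_freq = wander_freq, noise_sd = noise_sd,
                 st_shift = st_shift, t_amp = t_amp, r_amp = r_amp,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synthetic_config")
}

# P-QRS-T template as a sum of Gaussians, time relative to the R-peak
# (s). The R wave spans ~20 ms so an 80 ms QRS window captures Q, R
# and S completely; P and T sit well outside it. The ST offset is a
# broad bump centered 120 ms after R.
.beat_template <- function(t, r_amp = 1, t_amp = 0.3, st_shift = 0) {
  g <- function(mu, sd, a) a * exp(-(t - mu)^2 / (2 * sd^2))
  g(-0.200, 0.025, 0.12 * r_amp) +
    g(-0.028, 0.010, -0.10 * r_amp) +
    g(0.000, 0.006, r_amp) +
    g(0.028, 0.010, -0.15 * r_amp) +
    g(0.300, 0.050, t_amp) +
    g(0.120, 0.040, st_shift)
}

#' Generate a synthetic single-lead ECG with respiratory ground truth
#'
#' Beat times follow the heart-rate trajectory with optional Gaussian
#' interval jitter. Each beat renders a fixed sum-of-Gaussians P-QRS-T
#' template scaled by `1 + mod_depth * sin(phi(t_beat))`, where the
#' modulation phase advances at the instantaneous true respiratory
#' rate (`dphi/dt = 2 * pi * rr(t) / 60`). Sinusoidal baseline wander
#' and white noise are added last. The configured respiratory rate must
#' stay below half the beat rate everywhere (the beat-domain Nyquist
#' limit); an aliased modulation would be unrecoverable by construction
#' and is rejected.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_truth` with `record` (an [ecg_record()]),
#'   `beat_times` (s), `true_rr` (function of time, bpm), `modulation`
#'   (the per-beat scale factors actually applied) and `config`.
#' @export
generate_ecg <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config"))
    stop_config("`cfg` must come from synthetic_config()")
  hr_fun <- if (is.function(cfg$hr)) cfg$hr else {
    h <- cfg$hr; function(t) rep_len(h, length(t))
  }
  rr_fun <- if (is.function(cfg$rr)) cfg$rr else {
    r <- cfg$rr; function(t) rep_len(r, length(t))
  }
  grid <- seq(0, cfg$duration, by = 0.05)
  rrg <- rr_fun(grid)
  hrg <- hr_fun(grid)
  if (any(rrg >= hrg / 2))
    stop_config(paste0(
      "true RR reaches half the beat rate (beat-domain Nyquist); ",
      "an aliased modulation cannot be represented"))

  if (!is.null(cfg$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(cfg$seed)
  }

  # beat times: iterate the instantaneous interval plus jitter
  beat_times <- numeric(0)
  t <- 0.5
  while (t < cfg$duration - 0.45) {
    beat_times <- c(beat_times, t)
    iv <- 60 / hr_fun(t) +
      (if (cfg$hr_jitter_sd > 0) stats::rnorm(1, 0, cfg$hr_jitter_sd) else 0)
    t <- t + max(iv, 0.3)
  }
  if (length(beat_times) < 2L)
    stop_config("duration too short to place two beats")

  # respiratory modulation phase: integral of the instantaneous rate
  phase_grid <- 2 * pi / 60 * (cumsum(rrg) - rrg[1L]) * 0.05
  phi <- stats::approxfun(grid, phase_grid, rule = 2)
  scale <- 1 + cfg$mod_depth * sin(phi(beat_times))

  n <- round(cfg$duration * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  sig <- numeric(n)
  halfspan <- round(0.45 * cfg$fs)
  for (k in seq_along(beat_times)) {
    ic <- round(beat_times[k] * cfg$fs) + 1L
    lo <- max(1L, ic - halfspan); hi <- min(n, ic + halfspan)
    seg <- lo:hi
    sig[seg] <- sig[seg] + scale[k] *
      .beat_template(tt[seg] - beat_times[k], r_amp = cfg$r_amp,
                     t_amp = cfg$t_amp, st_shift = cfg$st_shift)
  }
  if (cfg$wander_amp > 0)
    sig <- sig + cfg$wander_amp * sin(2 * pi * cfg$wander_freq * tt)
  if (cfg$noise_sd > 0)
    sig <- sig + stats::rnorm(n, 0, cfg$noise_sd)

  structure(list(record = ecg_record(sig, fs = cfg$fs, label = "synthetic"),
                 beat_times = beat_times,
                 true_rr = rr_fun,
                 modulation = scale,
                 config = cfg),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %.0f s @ %g Hz, %d beats, true RR %s bpm\n",
    ecg_duration(x$record), x$record$fs, length(x$beat_times),
    if (is.function(x$config$rr)) "(protocol)" else format(x$config$rr)))
  invisible(x)
}
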