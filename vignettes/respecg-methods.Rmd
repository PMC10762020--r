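---
title: "ECG-derived respiratory rate: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-derived respiratory rate: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respecg)
```

## The signal model

Chest movement during breathing tilts the cardiac electrical axis and
changes the thoracic impedance path between heart and electrode, so the
projection of the QRS vector onto any single lead is amplitude-modulated
at the breathing frequency. `respecg` models the per-beat QRS
root-mean-square amplitude as

$$\mathrm{RMS}_k \approx A\,\bigl(1 + m \sin \varphi(t_k)\bigr),
\qquad \frac{d\varphi}{dt} = \frac{2\pi\,\mathrm{RR}(t)}{60},$$

where $t_k$ is the time of beat $k$, $m$ the modulation depth (a few
percent to ~10% in practice) and RR the respiratory rate in breaths
per minute. The estimator recovers the modulation frequency from the
sequence $\mathrm{RMS}_k$ — a *beat-domain* series, sampled once per
heartbeat — and converts cycles/beat to breaths/min with the mean R–R
interval of the analysis window.

Assumptions this rests on:

* QRS complexes are detectable and their amplitude is measured on a
  wander-free signal (both provided by the 8–40 Hz zero-phase
  bandpass).
* Respiration is slower than half the heart rate. One RMS sample per
  beat puts the beat-domain Nyquist limit at 0.5 cycles/beat; a
  breathing rate above half the beat rate aliases and is
  unrecoverable by *any* per-beat method. `estimate_rr()` warns when
  the configured band crosses this limit and clips the search there;
  the synthetic generator refuses to create such records.
* Within one 16-beat window the rate is roughly constant; beats are
  treated as evenly spaced and the window's mean R–R interval does the
  unit conversion. No Lomb–Scargle resampling is attempted — at the
  few-percent interval jitter of resting or anesthetized subjects the
  even-spacing error is far below the spectral grid spacing.

## Pipeline and parameters

| stage | parameter | default | why |
|---|---|---|---|
| bandpass | `band_low`–`band_high` | 8–40 Hz | passes QRS energy, rejects wander (<1 Hz), P/T waves and 50/60 Hz residue is tolerable after squaring |
| detector | `w_qrs` | 97 ms | matches QRS duration; the short moving average tracks QRS-scale energy |
| detector | `w_beat` | 611 ms | beat-scale energy baseline for the comparison |
| detector | `beta` | 0.08 | offset (times mean rectified energy) that suppresses noise-only blocks |
| detector | `refractory` | 200 ms | faster than any physiologic beat-to-beat interval |
| RMS | `qrs_window` | 80 ms | centered on the R-peak, captures Q–R–S but not P/T |
| spectrum | `spectral_window` | 16 beats | resolution/latency compromise (see below) |
| spectrum | `nfft` | 512 | zero-padding interpolates the spectrum to a 1/512 cycles/beat grid |
| band | `rr_band` | 1.8–18 bpm | 0.03–0.3 Hz at 60 beats/min, the conventional resting range; wide-range protocols (exercise, ventilator sweeps) use 5–40 bpm |
| smoother | `median_window` | 16 determinations | removes isolated mis-picks without tracking them |

All are exposed in `detection_config()` / `estimator_config()` and
reachable from the CLI. Window sizes of 8, 16, 32 and 64 beats form a
monotone trade-off: the test suite verifies on a stepped-rate record
that the 90%-settling delay after a rate step is non-decreasing in the
window length. 16 beats avoids both the coarse spectra of 8-beat
windows and the over-smoothing of 32/64-beat windows.

## Numerical choices

* **Zero-phase filtering** (`signal::filtfilt`) so that detected peak
  times are not skewed by filter group delay — the RMS windows are
  centered on those times.
* **Rectifier**: the detector squares the filtered signal by default
  (`rectifier = "abs"` is available). Squaring sharpens the
  QRS/background contrast and makes the block threshold scale
  quadratically, which keeps detection exactly invariant to positive
  amplitude rescaling — a property the suite asserts.
* **Detrending**: each 16-value RMS window is mean-subtracted before
  the transform. Without this, the DC lobe of a 16-point rectangular
  window leaks into the lowest bins and can beat genuine respiratory
  peaks at the bottom of the 1.8–18 bpm band.
* **Tie-break**: equal spectral maxima resolve to the lowest
  frequency, making output deterministic.
* **Timestamping**: each determination is stamped at the *last* beat
  of its spectral window, so the output is causal and suitable for
  streaming. The cost is an effective group delay of roughly half the
  spectral window plus half the median window (~16 beats in total);
  on rapidly drifting rates this appears as a small lag bias in
  cycle-to-cycle comparisons.
* **Median smoothing** uses a trailing window that shrinks at the
  start of the series, so output length equals input length and every
  smoothed value stays within the range of the raw values in its
  window (asserted as an invariant).
* **Resampling** is Fourier-domain (spectrum truncation /
  zero-padding, input padded to a 2-3-5-smooth length): band-limited
  content keeps its amplitude essentially exactly, which matters
  because R-wave amplitude is the measurand. A polyphase FIR
  alternative was evaluated and rejected: its passband ripple reached
  several percent on decimation, violating the 1–2% amplitude
  fidelity the RMS carrier needs.
* **Degenerate inputs**: an all-zero record yields an empty peak list
  (not an error); records too short for the detector windows or the
  spectral window raise classed input errors naming the shortfall;
  beats whose 80 ms window crosses a record edge are dropped with a
  message; spectral windows whose converted band contains no grid
  point are skipped and counted.

## Spectral grid accuracy and its limits

The zero-padded 512-point transform reads the peak off a 1/512
cycles/beat grid: at 60 beats/min one grid step is ≈0.12 bpm, which is
the quantization floor visible in steady-rate tests (mean absolute
errors of 0.03–0.05 bpm). Two caveats are documented rather than
hidden:

* Near the band edges the 16-sample rectangular window's spectral
  leakage — interference from the negative-frequency image — can bias
  the peak location by up to ~2 grid bins (measured at 0.10 and 0.41
  cycles/beat; phase-dependent). Mid-band frequencies
  (0.15–0.35 cycles/beat, e.g. 9–21 bpm at 60 beats/min) recover
  within one bin. This is intrinsic to short-window DFT peak picking,
  not to this implementation; the tests assert one-bin recovery
  mid-band and exact agreement with a brute-force DFT oracle
  everywhere.
* The R–R conversion makes the grid spacing proportional to heart
  rate: at 100 beats/min one bin is ≈0.20 bpm.

## The synthetic generator

`generate_ecg()` renders a sum-of-Gaussians P-QRS-T template (R width
≈20 ms, so the 80 ms QRS window contains the whole complex) at beat
times drawn from a constant or time-varying heart rate with Gaussian
interval jitter, scales each beat by $1 + m\sin\varphi(t)$, and adds
sinusoidal baseline wander and white noise. An `st_shift` raises the
ST segment and `t_amp` alters the T wave, emulating the morphology
change of acute ischemia; because the shift rides inside the scaled
template it changes the RMS *level*, not the modulation *frequency*,
which is exactly the robustness property the suite checks. All
randomness flows from one seed in a fixed order (per-beat jitter
first, then the noise vector), so records are bit-reproducible.

Default generator settings emulate an anesthetized, mechanically
ventilated subject: heart rate 60 beats/min with 10 ms interval
jitter, fixed 12 bpm ventilation, 10% modulation depth, 1 mV R wave,
0.02 mV noise (2% of R), 0.05 mV wander at 0.25 Hz. The stepped
protocol helper reproduces ventilator sweep experiments
(`stepped_protocol(c(11, 10, 12, 10, 11), 120)`), and
`smooth_protocol()` emulates spontaneous breathing whose rate drifts
slowly; the spontaneous test scenario sweeps 8→35→8 bpm over 10
minutes with heart rate covarying 60→100 beats/min, as in graded
exercise, which also keeps the rate below the beat-domain Nyquist
limit throughout.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show: respiratory sinus arrhythmia (frequency
modulation of the heart rate), respiration-correlated baseline wander
as an information channel, electrode motion artifacts, ectopic beats
and arrhythmias, and the lead-dependence of modulation depth. Accuracy
figures on synthetic records are ceilings for clean physiologic data,
not guarantees for noisy field recordings.

## Evaluation choices

* The headline R² is from an ordinary least-squares fit *with
  intercept* of estimates on reference; the identity-line R² is
  reported alongside because a fit R² alone can hide calibration
  offsets.
* TOST equivalence is computed on *paired* differences of the aligned
  cycle-to-cycle series (margin ±2 bpm, 90% confidence interval),
  matching the paired structure of an estimate-versus-reference
  comparison; with zero variance the interval degenerates to the
  point estimate.
* Rank-sum comparisons enumerate the exact null for tie-free groups
  of ≤10 and use the tie-corrected normal approximation otherwise;
  the suite checks the two agree to within 0.01 at n = 30.

## Problem sizes

The test suite and the acceptance script run entirely on generated
records: five 120 s steady records, one 600 s stepped record, one
600 s spontaneous-breathing record, and a grid of 90 s records over
RR ∈ {6, 10, 12, 18, 30} × HR ∈ {60, 90} (combinations below the
beat-domain Nyquist limit), all at 1000 Hz. These sizes give several
hundred pooled RR determinations per scenario — enough that the
accuracy statistics are stable to well under the quantities' test
tolerances — while the whole suite completes in well under a minute.

## Known limitations

* Single modulation channel: no fusion with frequency-modulation or
  baseline-wander respiration surrogates, and no multi-lead
  selection.
* The dual moving-average detector is the only detector implemented;
  other detectors can be plugged in by constructing an `rpeak_list()`
  from their output.
* Causal timestamping trades a ~16-beat lag for streaming
  suitability; retrospective analyses of fast rate transients may
  prefer to shift timestamps to the window center.
* No ectopic-beat rejection: a run of ectopy corrupts the RMS carrier
  until the median window flushes it.
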