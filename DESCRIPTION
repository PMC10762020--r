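Package: respecg
Title: Respiratory Rate Estimation from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates respiratory rate (breaths per minute) from a
    single-lead electrocardiogram by tracking the breath-induced
    amplitude modulation of the QRS complex. R-peaks are detected with
    a dual moving-average detector on an 8-40 Hz bandpassed signal,
    the root-mean-square amplitude of each QRS complex is computed in
    an 80 ms window, and the dominant beat-domain spectral peak of
    overlapping 16-beat RMS windows is converted to breaths per minute
    and median-smoothed. Includes readers for 16-bit binary, delimited
    text and WFDB format-16 records, a synthetic single-lead ECG
    generator with known respiratory ground truth, and an evaluation
    suite (absolute/relative error, linear fit, TOST equivalence,
    Wilcoxon rank-sum comparisons).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
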