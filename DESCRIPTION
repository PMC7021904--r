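Package: lfpburst
Title: Real-Time Detection of Narrow-Band Oscillation Bursts in Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline streaming emulation of a real-time burst detector for
    local field potentials: a bank of 32 narrow-band linear-phase FIR bandpass
    filters (1-32 Hz), power estimation by latching squared turning-point
    amplitudes, online artifact rejection, per-frequency dynamic percentile
    thresholds, and a neighbour-frequency peak test with duration gating and
    a reward state machine for closed-loop neurofeedback. Includes a surrogate
    generator (Gaussian-windowed sinusoid bursts in 1/f plus white noise),
    offline burst characterization on Morlet time-frequency representations,
    session-level power-change and training-effect statistics, and a
    method-comparison harness (wavelet, sliding FFT, variance-of-filtered)
    with a sum-of-squared-error metric and an adjacent-frequency resolution
    study (Wilcoxon rank-sum with label-permutation bootstrap).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
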