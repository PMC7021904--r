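---
title: "Detecting narrow-band oscillation bursts in streaming field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting narrow-band oscillation bursts in streaming field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpburst)
```

## The problem and the model

Local field potentials carry band-limited transients — beta "bursts" of a
few tens to a couple of hundred milliseconds — whose behavioural role can
only be probed causally if they are detected while they are still
happening. A detector usable in a closed loop must therefore be *causal*
(no future samples), *fast* (delay short enough for reinforcement to be
contingent on the event), and still resolve ~1 Hz in frequency and tens of
milliseconds in time.

`lfpburst` emulates such a detector sample by sample. Its model of a burst
is deliberately operational: a burst at frequency f exists at time t when
the narrow-band power at f exceeds the power of both neighbouring
frequencies *and* a subject- and time-specific statistical threshold. The
three ingredients are:

* **A bank of matched narrow-band filters.** Windowed-sinc FIR bandpass
  filters (order N = 256, 1 Hz passband, triangular window, unit gain at
  the center), centered at 1–32 Hz in 1 Hz steps. Linear phase means every
  frequency is delayed by exactly N/2 = 128 samples, so the per-frequency
  power estimates stay aligned and the neighbour comparison is meaningful
  at every single sample. The triangular window trades stopband depth for
  a narrow main lobe: the power response's full width at half maximum is
  about 5 Hz.
* **Extrema latching as a power estimate.** Squaring the amplitude at each
  detected peak/trough of the filtered signal and holding it until the
  next turning point yields a stepwise, strictly causal envelope-power
  estimate with a time resolution of half a period per frequency — no
  window, no additional delay beyond the filter's.
* **A dynamic percentile threshold.** Every second, the 98th percentile of
  the last 15 s of artifact-free power at each frequency. A percentile
  (rather than mean/SD) makes the threshold meaningful under the heavily
  skewed distribution of narrow-band power, and the sliding window absorbs
  slow drifts in overall power.

Assumptions worth stating: one channel, uniform sampling, noise and
ongoing activity locally stationary on the 15 s threshold timescale, and
bursts narrow-band enough that a 1 Hz-spaced bank separates them.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| sampling rate | 976.5625 | Hz | native rate of the emulated acquisition hardware (~1 kHz); all delays are derived from it |
| filter order N | 256 | samples | 128-sample group delay; FWHM ≈ 5 Hz at ~1 kHz |
| passband width | 1 | Hz | 1 Hz center spacing with heavy deliberate overlap |
| threshold percentile | 98 | – | ~2% supra-threshold time on stationary noise |
| threshold window | 15 | s | long enough for a stable upper percentile, short enough to track state changes |
| threshold update | 1 | s | threshold latency vs. cost trade-off |
| minimum duration | 70 | ms | reward gate; below it, supra-threshold flickers dominate |
| target band | 20–25 | Hz | example band; any sub-band of 2–31 Hz works (edge channels lack a neighbour) |
| artifact threshold | 500 | μV | on a 2–250 Hz 2nd-order Butterworth copy; ±500 ms pad |
| processing latency | 2 | ms | fixed computation budget added to event timestamps |
| reward volume/rate | 50 / 50 | μl, μl/s | delivery takes 1 s; +1 s lockout after rewards and artifacts |

`latency_ms()` reports the per-frequency detection latency on two clocks.
On the *nominal* clock the 128-sample delay is read as 128 ms under the
~1 kHz approximation, giving the conventional 130 ms total with the 2 ms
budget; on the *physical* clock 128 samples at 976.5625 Hz are 131.07 ms
(133.07 ms total). Samples are the ground truth; the millisecond figure is
a label.

Similarly, `filter_fwhm()` measures the width of the *power* response
(−3 dB points) by default, which is what the conventional "5 Hz" width of
this design refers to; the width at half of the *amplitude* response
(−6 dB) is 6.8 Hz and available via `response = "amplitude"`. Both are
found by bisection on the continuous response (tolerance 1e−4 Hz), not on
a grid.

## The surrogate generator

`synthesize()` builds ground-truth recordings: Gaussian-windowed sinusoids
`a · sin(2πf(t − t₀)) · exp(−(t − t₀)²/2σ²)` summed with 1/f ("pink")
noise and white noise. It emulates the two properties of LFP that matter
for this detector — a steep 1/f background against which narrow-band
events must be found, and band-limited transients of known frequency,
time, amplitude and width. It does *not* emulate non-sinusoidal burst
waveforms, phase–amplitude coupling, line noise, electrode drift, or
movement artifacts; passing tests on surrogates therefore demonstrates
correctness of the detection machinery at a known SNR, not performance on
any particular animal's recording.

Two generator choices are deliberate:

* **Noise "amplitude" is a peak amplitude.** The generator scales each
  noise realization so its maximum absolute value equals the requested
  amplitude (`normalize = "peak"`, the convention of the widely used
  peak-normalized pink-noise generators); an RMS mode is available. The
  peak reading keeps the unit consistent with the bursts' own amplitude
  parameter, and it is the only reading under which an amplitude-1 burst
  in amplitude-1.5 pink noise is detectable at all: with RMS-1.5 pink
  noise the burst's in-channel latched power (~0.21) sits at less than
  half the noise-only 98th-percentile threshold (~0.46), and no
  thresholding rule could recover it — inconsistent with the adjacent-
  frequency study being the method's showcase.
* **Envelope width σ defaults to 0.04 s** (envelope FWHM ≈ 94 ms, near
  the 70 ms duration gate and typical empirical burst durations). The
  width is a package default, configurable per burst.

## Numerical choices

* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), matching a plain sort-and-interpolate
  definition exactly.
* **Turning points** use a three-sample comparison emitted one sample
  after the extremum; on a plateau the *first* plateau sample is the
  extremum and detection happens one sample after the plateau ends
  (earliest causal, deterministic). Two same-kind candidates keep the more
  extreme one, so peaks and troughs strictly alternate. Power before a
  channel's first extremum is 0 (nothing latched yet).
* **Streaming equals batch.** Chunked filtering carries the filter history
  across chunk boundaries and reproduces whole-signal causal convolution
  bit for bit, for any chunking.
* **Threshold back-fill.** Masked (artifact) samples are excluded and the
  history window is extended backwards over older artifact-free samples,
  so the percentile always sees a full 15 s of valid data; before the
  first full window the threshold is "not ready" and nothing is flagged.
* **Ties fail.** The burst rule uses strict inequalities ("higher than"),
  so equal neighbour power or power equal to the threshold does not flag.
* **Offline burst peaks** are strict 8-neighbourhood local maxima of the
  TFR; on plateaus the earliest time, then lowest frequency wins.
* **Duration gating is per frequency channel** — a run must persist at one
  f — because the decision rule is defined per frequency. A burst that
  drifts between adjacent target frequencies splits into two sub-70 ms
  events under this rule; `band_union = TRUE` instead gates on the union
  of target-band flags (event frequency = strongest channel at the run's
  peak). Both are provided because the original behaviour for drifting
  bursts is unspecified.

## The comparison study and its conventions

`decompose()` implements four estimators on a common 1 ms grid: Morlet
wavelets (7 cycles offline / 3 online), sliding Hanning-window DFT (250 ms
offline / 150 ms online), variance of 1 Hz-bandpass-filtered signal
(150 ms offline / half-period online), and the filter-extrema pipeline.
The online wavelet/FFT/variation variants are the *parameter-reduced*
versions computed with centered kernels — the real-time constraint is
modelled by the shorter windows, which is what limits their resolution —
while filter-extrema is genuinely causal and is delay-compensated by
exactly N/2 samples when scored. The half-period latching lag is the
method's intrinsic resolution and is not compensated. `sse_metric()`
normalizes each method by a single scalar (its median over all trials)
before squaring and summing differences from the 7-cycle wavelet over
1000 ms × 12–32 Hz, so overall scale conventions cancel.

One estimator-specific caveat: the online variation method's half-period
variance window is phase-sensitive on a pure tone (the window *mean*
oscillates at the tone frequency), so its power ripples ~20% there by
construction; this is a property of the estimator, not an implementation
artifact.

The adjacent-frequency resolution study (`resolution_study()`) plants two
amplitude-1 bursts at 20 and 21 Hz per 10 s trace (pink 1.5, white 0.3),
detects with the filter-extrema pipeline and a whole-trace 98th-percentile
threshold (a 10 s trace cannot fill the 15 s dynamic window), and scores
the first-vs-second-burst frequency samples with a Wilcoxon rank-sum z
(normal approximation, midranks, tie correction) and a label-permutation
bootstrap preserving group sizes. The study scores detected *peaks*
(`min_duration_ms = 0`): the 70 ms gate belongs to the reward path, and at
the study's SNR the asynchronous per-channel latch updates chop
supra-threshold runs below 70 ms, which would measure the gate rather than
the frequency resolution.

## Problem sizes

The shipped tests run entirely on synthetic data: traces of 2–66 s for
unit tests, 50 repetitions × 10 s with a 10,000-draw bootstrap for the
resolution study, and a 100-trial (≈350 s) benchmark for the SSE
comparison. These sizes give stable test statistics while keeping a full
suite run in the low minutes on one core.

## Known limitations

* Single-channel only; no multi-channel artifact consensus or referencing.
* The emulation is deterministic and offline; it reproduces the *logic* of
  a hard-real-time system, not its scheduling jitter.
* The EDF reader/writer is minimal (continuous recordings, 16-bit
  integer samples) and intended for interchange of modest traces.
* Filters are fixed at design time; no adaptive redesign within a session
  and no IIR alternatives.
* Edge channels (1 and 32 Hz) can never flag — a target band must stay
  within 2–31 Hz.
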