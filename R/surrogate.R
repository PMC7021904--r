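# Surrogate LFP generator: Gaussian-windowed sinusoid bursts of known
# frequency, time and amplitude, embedded in 1/f ("pink") noise plus white
# noise. Provides the ground truth against which detector performance is
# measured.

#' Gaussian-windowed sinusoid burst
#'
#' `amplitude * sin(2*pi*f*(t - t0)) * exp(-(t - t0)^2 / (2*sigma^2))`,
#' zero-phase at the envelope center.
#'
#' @param frequency Hz.
#' @param center_time envelope center t0, seconds.
#' @param sigma envelope standard deviation, seconds (> 0).
#' @param amplitude sinusoid peak amplitude.
#' @param sampling_rate Hz.
#' @param duration trace length, seconds.
#' @return numeric waveform of `round(duration * sampling_rate)` samples.
#' @export
make_burst <- function(frequency, center_time, sigma, amplitude,
                       sampling_rate, duration) {
  if (sigma <= 0) stop("envelope sigma must be positive")
  stopifnot(frequency < sampling_rate / 2)
  t <- (seq_len(round(duration * sampling_rate)) - 1) / sampling_rate
  amplitude * sin(2 * pi * frequency * (t - center_time)) *
    exp(-(t - center_time)^2 / (2 * sigma^2))
}

#' Pink (1/f) noise
#'
#' White Gaussian noise shaped in the frequency domain so the amplitude
#' spectrum scales as `1/sqrt(f)` (power as `1/f`), then rescaled to the
#' requested amplitude. `normalize = "peak"` (default) scales the
#' realization so its maximum absolute value equals `amplitude`, the
#' convention of the usual peak-normalized pink-noise generators and the
#' one under which planted unit-amplitude bursts remain detectable above
#' the noise; `"rms"` scales to a root-mean-square of `amplitude` instead.
#' Deterministic given `seed`; with `seed = NULL` the current RNG stream is
#' used.
#'
#' @param n number of samples (> 0).
#' @param amplitude target peak (or RMS) amplitude.
#' @param seed optional integer seed.
#' @param normalize `"peak"` or `"rms"`.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, amplitude, seed = NULL,
                       normalize = c("peak", "rms")) {
  normalize <- match.arg(normalize)
  if (n <= 0) stop("n must be positive")
  if (amplitude == 0) return(numeric(n))
  w <- if (is.null(seed)) stats::rnorm(n) else with_seed(seed, stats::rnorm(n))
  X <- stats::fft(w)
  # frequency-bin magnitudes: bin k (0-based) <-> k/n cycles/sample; shape by
  # 1/sqrt(f) with DC removed, keeping Hermitian symmetry so the result is real
  k <- 0:(n - 1)
  fbin <- pmin(k, n - k)            # symmetric bin index
  scale <- ifelse(fbin == 0, 0, 1 / sqrt(fbin))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  denom <- if (normalize == "peak") max(abs(x)) else sqrt(mean(x^2))
  x * amplitude / denom
}

#' White Gaussian noise at a target amplitude
#'
#' @inheritParams pink_noise
#' @export
white_noise <- function(n, amplitude, seed = NULL,
                        normalize = c("peak", "rms")) {
  normalize <- match.arg(normalize)
  if (n <= 0) stop("n must be positive")
  if (amplitude == 0) return(numeric(n))
  w <- if (is.null(seed)) stats::rnorm(n) else with_seed(seed, stats::rnorm(n))
  denom <- if (normalize == "peak") max(abs(w)) else sqrt(mean(w^2))
  w * amplitude / denom
}

#' Describe a synthetic recording
#'
#' @param sampling_rate Hz (default 976.5625, the detector's native rate).
#' @param duration seconds.
#' @param bursts data.frame with columns `frequency`, `center_time`, `sigma`,
#'   `amplitude` (one planted burst per row); may be empty.
#' @param pink_amplitude RMS of the 1/f noise floor (default 1.5).
#' @param white_amplitude RMS of the white noise (default 0.3).
#' @param seed integer seed; the same spec reproduces the identical trace.
#' @return object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(sampling_rate = 976.5625, duration = 10,
                           bursts = data.frame(frequency = numeric(0),
                                               center_time = numeric(0),
                                               sigma = numeric(0),
                                               amplitude = numeric(0)),
                           pink_amplitude = 1.5, white_amplitude = 0.3,
                           seed = 1L) {
  stopifnot(is.data.frame(bursts),
            all(c("frequency", "center_time", "sigma", "amplitude") %in%
                  names(bursts)),
            pink_amplitude >= 0, white_amplitude >= 0, duration > 0,
            is.finite(seed), abs(seed) < 2^31)
  if (nrow(bursts) > 0L) {
    stopifnot(all(bursts$frequency < sampling_rate / 2),
              all(bursts$amplitude >= 0), all(bursts$sigma > 0))
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 bursts = bursts, pink_amplitude = pink_amplitude,
                 white_amplitude = white_amplitude, seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Standard two-burst spec: adjacent frequencies in pink + white noise
#'
#' The resolution-study configuration: two Gaussian bursts of amplitude 1 at
#' 20 and 21 Hz, embedded in 1/f noise of amplitude 1.5 and white noise of
#' amplitude 0.3.
#'
#' @param seed integer seed.
#' @param frequencies the two burst frequencies, Hz.
#' @param times burst center times, seconds.
#' @param sigma envelope width, seconds (default 0.04).
#' @param amplitude burst amplitude (default 1).
#' @param ... passed to [surrogate_spec()].
#' @export
adjacent_burst_spec <- function(seed = 1L, frequencies = c(20, 21),
                                times = c(3.5, 6.5), sigma = 0.04,
                                amplitude = 1, ...) {
  surrogate_spec(bursts = data.frame(frequency = frequencies,
                                     center_time = times,
                                     sigma = sigma, amplitude = amplitude),
                 seed = seed, ...)
}

#' Synthesize a surrogate recording
#'
#' Sums all planted burst waveforms with seeded pink and white noise, and
#' returns the trace together with a ground-truth burst table (onset
#' `t0 - 2*sigma`, duration `4*sigma`).
#'
#' @param spec a `surrogate_spec`.
#' @return list with `stream` (a `sample_stream`) and `truth` (data.frame
#'   `frequency`, `center_time`, `onset_s`, `duration_s`, `amplitude`).
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  x <- numeric(n)
  for (k in seq_len(nrow(spec$bursts))) {
    b <- spec$bursts[k, ]
    x <- x + make_burst(b$frequency, b$center_time, b$sigma, b$amplitude,
                        spec$sampling_rate, spec$duration)
  }
  noise <- with_seed(spec$seed, {
    pink_noise(n, spec$pink_amplitude) + white_noise(n, spec$white_amplitude)
  })
  truth <- data.frame(frequency = spec$bursts$frequency,
                      center_time = spec$bursts$center_time,
                      onset_s = spec$bursts$center_time - 2 * spec$bursts$sigma,
                      duration_s = 4 * spec$bursts$sigma,
                      amplitude = spec$bursts$amplitude)
  list(stream = sample_stream(x + noise, spec$sampling_rate), truth = truth)
}
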