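# Shared fixtures, built once per test run.

FS <- 976.5625

# the full 1-32 Hz bank is used by several files; build it once
the_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_bank(FS)
    bank
  }
})

tone_stream <- function(freq, amplitude = 1, duration = 4, fs = FS,
                        phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  sample_stream(amplitude * sin(2 * pi * freq * t + phase), fs)
}

steady_cols <- function(stream, from_s, to_s) {
  round(from_s * stream$sampling_rate):round(to_s * stream$sampling_rate)
}

# sort-based percentile oracle: linear interpolation between order statistics
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p / 100 + 1
  k <- floor(h)
  g <- h - k
  if (k >= length(xs)) xs[length(xs)] else (1 - g) * xs[k] + g * xs[k + 1]
}
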