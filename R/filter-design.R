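# Narrow-band linear-phase FIR bandpass design: windowed sinc with a
# triangular (Bartlett) window, magnitude response normalized to unity at the
# passband center. This is the filter the streaming detector runs per
# frequency channel.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

filter_window <- function(kind, n) {
  # n = order + 1 taps
  switch(kind,
    bartlett = {
      half <- (n - 1) / 2
      1 - abs(seq_len(n) - 1 - half) / half   # endpoints zero
    },
    kaiser12 = {
      # Kaiser window for a 12 dB stopband: beta = 0 by the standard Kaiser
      # design formula (attenuation below 21 dB), i.e. rectangular.
      rep(1, n)
    },
    stop("unknown window kind: ", kind)
  )
}

#' Design one narrow-band linear-phase FIR bandpass filter
#'
#' Windowed-sinc bandpass of even order `order` with passband
#' `[center_freq - half_bw, center_freq + half_bw]` Hz (1 Hz wide by default),
#' tapered by a triangular (Bartlett) window of length `order + 1`, and
#' normalized so that the magnitude response at `center_freq` is exactly 1.
#' With the defaults (order 256, sampling rate 976.5625 Hz) the power response
#' has a full width at half maximum of about 5 Hz and the group delay is
#' `order / 2` samples at every frequency.
#'
#' @param center_freq passband center, Hz.
#' @param order filter order N (even, >= 2); the filter has N + 1 taps.
#' @param sampling_rate sampling rate, Hz.
#' @param half_bw half passband width, Hz (default 0.5, i.e. a 1 Hz passband).
#' @param window window taper: `"bartlett"` (default) or `"kaiser12"`.
#' @return an object of class `filter_spec`: list with `center_freq`,
#'   `passband_low`, `passband_high`, `order`, `sampling_rate`,
#'   `coefficients` (length N + 1, symmetric), `normalized` (TRUE).
#' @export
design_bandpass <- function(center_freq, order = 256L, sampling_rate = 976.5625,
                            half_bw = 0.5, window = "bartlett") {
  stopifnot(is.numeric(center_freq), length(center_freq) == 1L,
            is.numeric(order), length(order) == 1L,
            is.numeric(sampling_rate), sampling_rate > 0, half_bw > 0)
  if (order < 2 || order %% 2 != 0)
    stop("filter order must be even and >= 2 (group delay must be an ",
         "integer number of samples); got ", order)
  nyq <- sampling_rate / 2
  if (center_freq <= half_bw || center_freq >= nyq - half_bw)
    stop("center frequency ", center_freq, " Hz too close to 0 or Nyquist (",
         nyq, " Hz) for a ", 2 * half_bw, " Hz passband")
  f1 <- center_freq - half_bw
  f2 <- center_freq + half_bw
  k <- 0:order
  m <- k - order / 2
  h <- 2 * (f2 / sampling_rate) * sinc(2 * f2 / sampling_rate * m) -
       2 * (f1 / sampling_rate) * sinc(2 * f1 / sampling_rate * m)
  b <- h * filter_window(window, order + 1L)
  gain <- Mod(sum(b * exp(-2i * pi * center_freq * k / sampling_rate)))
  b <- b / gain
  structure(list(center_freq = center_freq,
                 passband_low = f1, passband_high = f2,
                 order = as.integer(order),
                 sampling_rate = sampling_rate,
                 coefficients = b,
                 normalized = TRUE),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> bandpass %.2f-%.2f Hz (center %.2f), order %d, Fs %.4f Hz\n",
    x$passband_low, x$passband_high, x$center_freq, x$order, x$sampling_rate))
  invisible(x)
}

#' Magnitude response of a FIR filter on a frequency grid
#'
#' @param spec a `filter_spec`.
#' @param freqs frequencies in Hz, within `[0, sampling_rate / 2]`.
#' @return `|H(f)|` for each grid frequency.
#' @export
magnitude_response <- function(spec, freqs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (length(freqs) == 0L) stop("empty frequency grid")
  if (any(freqs < 0 | freqs > spec$sampling_rate / 2))
    stop("frequency grid must lie within [0, Fs/2]")
  k <- 0:spec$order
  vapply(freqs, function(f)
    Mod(sum(spec$coefficients * exp(-2i * pi * f * k / spec$sampling_rate))),
    numeric(1))
}

#' Full width at half maximum of a bandpass filter's response
#'
#' Distance in Hz between the two frequencies nearest the passband center at
#' which the response crosses half its (unit) peak, located by bisection on
#' the continuous frequency response to `tol` Hz. The width is measured on
#' the power response `|H|^2` by default, the usual -3 dB bandwidth; with
#' `response = "amplitude"` the width where `|H|` itself halves (-6 dB) is
#' returned instead.
#'
#' @param spec a normalized `filter_spec`.
#' @param response `"power"` (default) or `"amplitude"`.
#' @param tol bisection tolerance, Hz.
#' @return width in Hz.
#' @export
filter_fwhm <- function(spec, response = c("power", "amplitude"), tol = 1e-4) {
  stopifnot(inherits(spec, "filter_spec"), isTRUE(spec$normalized))
  response <- match.arg(response)
  H <- function(f) {
    m <- magnitude_response(spec, f)
    if (response == "power") m^2 else m
  }
  fc <- spec$center_freq
  nyq <- spec$sampling_rate / 2
  bisect <- function(lo, hi) {
    # invariant: H(lo) and H(hi) straddle 0.5 (in either frequency order)
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if ((H(mid) >= 0.5) == (H(lo) >= 0.5)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  find_cross <- function(dir) {
    # march out from the center until the response falls below 0.5
    step <- 0.25
    f <- fc
    repeat {
      nxt <- f + dir * step
      if (nxt <= 0 || nxt >= nyq)
        stop("response never falls below half maximum on ",
             if (dir < 0) "the low" else "the high", " side")
      if (H(nxt) < 0.5) return(bisect(f, nxt))
      f <- nxt
    }
  }
  find_cross(+1) - find_cross(-1)
}

#' Group delay of a symmetric (linear-phase) FIR filter, in samples
#'
#' @param spec a `filter_spec` with symmetric coefficients.
#' @return integer delay `order / 2` in samples.
#' @export
group_delay_samples <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  b <- spec$coefficients
  if (max(abs(b - rev(b))) > 1e-12 * max(abs(b)))
    stop("coefficients are not symmetric; group delay is not ",
         "frequency-independent")
  as.integer(spec$order / 2)
}

#' Group delay in seconds
#' @param spec a `filter_spec`.
#' @return delay in seconds, `(order / 2) / sampling_rate`.
#' @export
group_delay_seconds <- function(spec) {
  group_delay_samples(spec) / spec$sampling_rate
}

#' Per-frequency detection latency in milliseconds
#'
#' Group delay plus a fixed computation budget. On the `"nominal"` clock the
#' sample delay is read as milliseconds under the ~1 kHz approximation
#' (order/2 = 128 samples -> 128 ms, total 130 ms with the default 2 ms
#' budget); `"physical"` converts samples at the true sampling rate
#' (131.07 ms + budget at Fs = 976.5625 Hz).
#'
#' @param spec a `filter_spec`.
#' @param computation_ms processing-time budget, ms (default 2).
#' @param clock `"nominal"` or `"physical"`.
#' @return latency in ms.
#' @export
latency_ms <- function(spec, computation_ms = 2, clock = c("nominal", "physical")) {
  clock <- match.arg(clock)
  d <- group_delay_samples(spec)
  delay_ms <- if (clock == "nominal") d else d / spec$sampling_rate * 1000
  delay_ms + computation_ms
}

#' Build the filter bank
#'
#' One narrow-band bandpass per center frequency, all sharing the same order
#' and sampling rate (hence identical group delay). Defaults reproduce the
#' detector's bank: centers 1 to 32 Hz in 1 Hz steps, order 256.
#'
#' @param sampling_rate Hz.
#' @param centers center frequencies, Hz, strictly increasing.
#' @param order common filter order.
#' @return an object of class `filter_bank`: list with `filters` (named list
#'   of `filter_spec`), `centers`, `order`, `sampling_rate`.
#' @export
build_bank <- function(sampling_rate = 976.5625, centers = 1:32, order = 256L) {
  stopifnot(length(centers) >= 1L, all(diff(centers) > 0))
  filters <- lapply(centers, function(fc) {
    tryCatch(design_bandpass(fc, order, sampling_rate),
             error = function(e)
               stop("center ", fc, " Hz rejected: ", conditionMessage(e),
                    call. = FALSE))
  })
  names(filters) <- as.character(centers)
  structure(list(filters = filters, centers = as.numeric(centers),
                 order = as.integer(order), sampling_rate = sampling_rate),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d filters, centers %g-%g Hz, order %d, Fs %.4f Hz\n",
              length(x$filters), min(x$centers), max(x$centers), x$order,
              x$sampling_rate))
  invisible(x)
}

#' Export a filter bank as delimited text
#'
#' One row per filter: center frequency followed by the coefficients.
#' @param bank a `filter_bank`.
#' @param path output file.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  rows <- t(vapply(bank$filters, function(f) c(f$center_freq, f$coefficients),
                   numeric(bank$order + 2L)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
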