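# Causal streaming emulation of the per-frequency DSP chain: narrow-band
# filtering, turning-point detection, power latching (square of the last
# extremum amplitude, held until the next one), and sawtooth phase estimation
# with group-delay compensation.

#' Construct a uniformly sampled signal
#'
#' @param values signal values (microvolts for recordings).
#' @param sampling_rate Hz.
#' @param start_time seconds.
#' @return an object of class `sample_stream`.
#' @export
sample_stream <- function(values, sampling_rate, start_time = 0) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            is.numeric(sampling_rate), sampling_rate > 0)
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "sample_stream")
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("<sample_stream> %d samples at %.4f Hz (%.2f s)\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate))
  invisible(x)
}

stream_times <- function(stream) {
  stream$start_time + (seq_along(stream$values) - 1) / stream$sampling_rate
}

causal_fir <- function(b, x) as.numeric(signal::filter(b, 1, x))

#' Filter a signal through the whole bank (causal)
#'
#' Causal FIR convolution per channel: the output at sample n depends only on
#' inputs at or before n, and every channel carries the same fixed group
#' delay of `order / 2` samples. With `chunk_size` the input is processed in
#' consecutive chunks while carrying the filter history forward, which
#' reproduces whole-signal filtering bit for bit (used to emulate streaming
#' acquisition buffers).
#'
#' @param bank a `filter_bank`.
#' @param stream a `sample_stream` with matching sampling rate.
#' @param chunk_size optional streaming chunk length in samples.
#' @return matrix of filtered signals, one row per filter, rownames = center
#'   frequencies.
#' @export
stream_filter <- function(bank, stream, chunk_size = NULL) {
  stopifnot(inherits(bank, "filter_bank"), inherits(stream, "sample_stream"))
  if (abs(stream$sampling_rate - bank$sampling_rate) >
      1e-9 * bank$sampling_rate)
    stop("stream sampling rate does not match the bank")
  x <- stream$values
  if (length(x) <= bank$order)
    stop("stream shorter than the filter order (", bank$order, " samples)")
  out <- matrix(0, nrow = length(bank$filters), ncol = length(x),
                dimnames = list(as.character(bank$centers), NULL))
  for (i in seq_along(bank$filters)) {
    b <- bank$filters[[i]]$coefficients
    if (is.null(chunk_size)) {
      out[i, ] <- causal_fir(b, x)
    } else {
      stopifnot(chunk_size >= 1L)
      starts <- seq(1L, length(x), by = chunk_size)
      hist <- numeric(0)
      for (s in starts) {
        e <- min(s + chunk_size - 1L, length(x))
        y <- causal_fir(b, c(hist, x[s:e]))
        out[i, s:e] <- y[(length(hist) + 1L):length(y)]
        hist <- utils::tail(c(hist, x[s:e]), bank$order)
      }
    }
  }
  out
}

#' Detect turning points (peaks and troughs) in a filtered channel
#'
#' Local extrema by three-sample comparison, causally: an extremum at sample
#' i is emitted once the following sample confirms the direction change
#' (`detect_index` = first sample after the extremum or, on a plateau, after
#' the plateau ends; the extremum itself is the plateau's first sample).
#' Peaks and troughs strictly alternate; of two same-kind candidates the more
#' extreme one is kept.
#'
#' @param x numeric vector (one filtered channel).
#' @return data.frame with `index`, `detect_index`, `kind` ("peak"/"trough"),
#'   `amplitude`.
#' @export
detect_turning_points <- function(x) {
  empty <- data.frame(index = integer(0), detect_index = integer(0),
                      kind = character(0), amplitude = numeric(0))
  n <- length(x)
  if (n < 3L) return(empty)
  d <- diff(x)
  s <- sign(d)                       # s[i]: direction from sample i to i+1
  nz <- which(s != 0)
  if (length(nz) < 2L) return(empty)
  # carry the next nonzero direction backwards over plateaus, so a plateau
  # belongs to its exit direction and the extremum lands on its first sample
  s_filled <- s
  idx <- seq_len(n - 1L)
  last_nz <- nz[findInterval(idx, nz, left.open = TRUE) + 1L]
  keep <- !is.na(last_nz)
  s_filled[idx[keep]] <- s[last_nz[keep]]
  s_filled[idx[!keep]] <- 0
  turns <- which(s_filled[-1L] != 0 & s_filled[-length(s_filled)] != 0 &
                 s_filled[-1L] != s_filled[-length(s_filled)]) + 1L
  if (length(turns) == 0L) return(empty)
  kind <- ifelse(s_filled[turns] < 0, "peak", "trough")
  # causal detection: one sample after the direction change is observed;
  # on a plateau that is one sample past the plateau's last sample
  detect <- vapply(turns, function(i) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    min(j + 1L, n)
  }, integer(1))
  ev <- data.frame(index = turns, detect_index = detect, kind = kind,
                   amplitude = x[turns], stringsAsFactors = FALSE)
  enforce_alternation(ev)
}

enforce_alternation <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  keep <- rep(TRUE, nrow(ev))
  last <- 1L
  for (i in 2L:nrow(ev)) {
    if (ev$kind[i] == ev$kind[last]) {
      better <- if (ev$kind[i] == "peak")
        ev$amplitude[i] > ev$amplitude[last]
      else ev$amplitude[i] < ev$amplitude[last]
      if (better) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
    } else last <- i
  }
  ev[keep, , drop = FALSE]
}

#' Latch extremum power into a stepwise per-sample track
#'
#' The square of each turning point's amplitude becomes the power estimate
#' and is held from the sample at which the extremum is detected until the
#' next detection; before the first extremum the power is 0. This gives a
#' time resolution of half the period of the channel frequency.
#'
#' @param extrema data.frame from [detect_turning_points()], sorted by index.
#' @param length output track length in samples.
#' @param frequency optional channel frequency tag, Hz.
#' @return object of class `power_track`: list with `values` (length
#'   `length`), `update_indices`, `frequency`.
#' @export
latch_power <- function(extrema, length, frequency = NA_real_) {
  stopifnot(is.numeric(length), length >= 0)
  n <- as.integer(length)
  if (nrow(extrema) > 0L && is.unsorted(extrema$index))
    stop("extrema must be sorted by sample index")
  values <- numeric(n)
  upd <- integer(0)
  if (nrow(extrema) > 0L) {
    di <- pmin(extrema$detect_index, n)
    p <- extrema$amplitude^2
    upd <- di[di <= n]
    bounds <- c(di, n + 1L)
    for (j in seq_along(di)) {
      if (di[j] <= n)
        values[di[j]:(bounds[j + 1L] - 1L)] <- p[j]
    }
  }
  structure(list(values = values, update_indices = upd, frequency = frequency),
            class = "power_track")
}

#' Phase-reset delay for group-delay compensation
#'
#' The sawtooth phase estimate is reset a delay `delta(f) = ceiling(d/T)*T - d`
#' seconds after each detected extremum, where `d` is the filter group delay
#' in seconds and `T = 1/f`; this schedules the reset onto the next assumed
#' true peak (or trough) of the undelayed signal.
#'
#' @param frequency channel frequency, Hz (> 0).
#' @param group_delay_s group delay in seconds.
#' @return delay in seconds, in `[0, T)`.
#' @export
phase_reset_delay <- function(frequency, group_delay_s) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  T <- 1 / frequency
  ceiling(group_delay_s / T) * T - group_delay_s
}

#' Sawtooth phase estimate from detected extrema
#'
#' A sawtooth of slope `2*pi*f` (modulo `2*pi`); `delta(f)` seconds after
#' each extremum detection the phase is reset to 0 (peak) or `pi` (trough),
#' compensating the filter group delay.
#'
#' @param extrema data.frame from [detect_turning_points()].
#' @param frequency channel frequency, Hz.
#' @param sampling_rate Hz.
#' @param group_delay_s filter group delay, seconds.
#' @param length output length in samples.
#' @return numeric vector of phases in `[0, 2*pi)`.
#' @export
estimate_phase <- function(extrema, frequency, sampling_rate, group_delay_s,
                           length) {
  if (frequency <= 0) stop("frequency must be positive")
  n <- as.integer(length)
  delta <- phase_reset_delay(frequency, group_delay_s)
  step <- 2 * pi * frequency / sampling_rate
  phase <- (seq_len(n) - 1) * step
  if (nrow(extrema) > 0L) {
    reset_idx <- extrema$detect_index + as.integer(round(delta * sampling_rate))
    target <- ifelse(extrema$kind == "peak", 0, pi)
    ok <- reset_idx >= 1L & reset_idx <= n
    reset_idx <- reset_idx[ok]; target <- target[ok]
    # after each reset the sawtooth restarts from the target value
    offset <- numeric(n)
    base <- 0
    bounds <- c(reset_idx, n + 1L)
    if (length(reset_idx) > 0L) {
      for (j in seq_along(reset_idx)) {
        i0 <- reset_idx[j]
        base <- target[j] - (i0 - 1) * step
        offset[i0:(bounds[j + 1L] - 1L)] <- base - 0
      }
      phase <- phase + offset
    }
  }
  phase %% (2 * pi)
}

#' Run the full streaming power pipeline
#'
#' Filters the stream through the bank, detects turning points per channel,
#' and latches extremum power into per-sample stepwise tracks.
#'
#' @param stream a `sample_stream`.
#' @param bank a `filter_bank` (default: the 1-32 Hz bank at the stream's
#'   sampling rate).
#' @param chunk_size optional streaming chunk size (see [stream_filter()]).
#' @param keep_filtered keep the filtered channel matrix in the result.
#' @return list with `power` (matrix, rows = center frequencies), `extrema`
#'   (list of data.frames per channel), `bank`, and optionally `filtered`.
#' @export
run_pipeline <- function(stream, bank = NULL, chunk_size = NULL,
                         keep_filtered = FALSE) {
  stopifnot(inherits(stream, "sample_stream"))
  if (is.null(bank)) bank <- build_bank(stream$sampling_rate)
  filt <- stream_filter(bank, stream, chunk_size = chunk_size)
  n <- ncol(filt)
  power <- matrix(0, nrow = nrow(filt), ncol = n, dimnames = dimnames(filt))
  extrema <- vector("list", nrow(filt))
  names(extrema) <- rownames(filt)
  for (i in seq_len(nrow(filt))) {
    ev <- detect_turning_points(filt[i, ])
    extrema[[i]] <- ev
    power[i, ] <- latch_power(ev, n, frequency = bank$centers[i])$values
  }
  out <- list(power = power, extrema = extrema, bank = bank)
  if (keep_filtered) out$filtered <- filt
  out
}

#' Export a power matrix as delimited text
#'
#' Rows = frequencies, columns = samples; first column is the frequency.
#' @param power matrix with frequency rownames.
#' @param path output file.
#' @export
write_power <- function(power, path) {
  df <- data.frame(frequency_hz = rownames(power), power, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
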