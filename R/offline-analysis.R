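# Offline burst characterization: time-frequency representations (complex
# Morlet wavelets or sliding Hanning-window DFT at 1 ms steps), detection of
# bursts as local maxima in the time-frequency plane above a per-frequency
# percentile, time-locked averaging aligned to the last beta trough before an
# event, and the session-level power-change and training-effect statistics.

# Convolve a real signal with a centered complex kernel via FFT; returns the
# aligned complex series (same length as x).
kernel_conv <- function(x, w) {
  n <- length(x); L <- length(w)
  stopifnot(L %% 2L == 1L)
  N <- stats::nextn(n + L - 1L, 2L)
  X <- stats::fft(c(x, rep(0, N - n)))
  W <- stats::fft(c(w, rep(0, N - L)))
  y <- stats::fft(X * W, inverse = TRUE) / N
  mid <- (L + 1L) / 2L
  y[mid:(mid + n - 1L)]
}

morlet_kernel <- function(frequency, fs, cycles, gwidth = 3.5) {
  sigma_t <- cycles / (2 * pi * frequency)
  h <- ceiling(gwidth * sigma_t * fs)
  t <- (-h:h) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  env * exp(1i * 2 * pi * frequency * t) * 2 / sum(env)  # unit tone -> |y|=A
}

hanning_kernel <- function(frequency, fs, window_ms) {
  L <- round(window_ms / 1000 * fs)
  if (L %% 2L == 0L) L <- L + 1L
  t <- (-(L - 1L) / 2):((L - 1L) / 2) / fs
  env <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann, zero endpoints
  env * exp(1i * 2 * pi * frequency * t) * 2 / sum(env)
}

new_tfr <- function(power, freqs, times_s, method, sampling_rate) {
  structure(list(power = power, freqs = freqs, times_s = times_s,
                 method = method, sampling_rate = sampling_rate,
                 normalization = "none"),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %s: %d freqs (%g-%g Hz) x %d time points\n", x$method,
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times_s)))
  invisible(x)
}

# evaluate per-sample power rows on a millisecond time grid
resample_rows <- function(P, sample_times, times_out,
                          interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  out <- matrix(0, nrow(P), length(times_out))
  for (i in seq_len(nrow(P)))
    out[i, ] <- stats::approx(sample_times, P[i, ], xout = times_out,
                              method = interp, rule = 2, f = 0)$y
  out
}

tfr_time_grid <- function(stream, step_ms) {
  t <- stream_times(stream)
  seq(t[1], t[length(t)], by = step_ms / 1000)
}

kernel_tfr <- function(stream, freqs, kernel_fun, method, step_ms) {
  stopifnot(inherits(stream, "sample_stream"))
  fs <- stream$sampling_rate
  if (any(freqs >= fs / 2)) stop("requested frequency at or above Nyquist")
  times_out <- tfr_time_grid(stream, step_ms)
  P <- matrix(0, length(freqs), length(stream$values))
  for (i in seq_along(freqs))
    P[i, ] <- Mod(kernel_conv(stream$values, kernel_fun(freqs[i], fs)))^2
  power <- resample_rows(P, stream_times(stream), times_out)
  rownames(power) <- as.character(freqs)
  new_tfr(power, freqs, times_out, method, fs)
}

#' Morlet wavelet time-frequency representation
#'
#' Magnitude-squared complex Morlet convolution, evaluated in `step_ms`
#' steps. The wavelet width is `cycles` cycles (Gaussian envelope SD
#' `cycles / (2*pi*f)`); kernels are scaled so a sinusoid of amplitude A
#' yields power A^2 at its frequency.
#'
#' @param stream a `sample_stream`.
#' @param freqs analysis frequencies, Hz.
#' @param cycles wavelet width in cycles (default 7).
#' @param step_ms time step of the output grid, ms (default 1).
#' @return a `tfr`.
#' @export
morlet_tfr <- function(stream, freqs, cycles = 7, step_ms = 1) {
  stopifnot(cycles >= 1)
  kernel_tfr(stream, freqs,
             function(f, fs) morlet_kernel(f, fs, cycles),
             sprintf("morlet-%g", cycles), step_ms)
}

#' Sliding Hanning-window DFT time-frequency representation
#'
#' Power at each requested frequency from a Hanning-tapered window of fixed
#' length centered on each output time, in `step_ms` steps.
#'
#' @inheritParams morlet_tfr
#' @param window_ms window length, ms (e.g. 250 offline, 150 online).
#' @return a `tfr`.
#' @export
fft_tfr <- function(stream, freqs, window_ms = 250, step_ms = 1) {
  kernel_tfr(stream, freqs,
             function(f, fs) hanning_kernel(f, fs, window_ms),
             sprintf("fft-%g", window_ms), step_ms)
}

#' Variance-of-filtered time-frequency representation
#'
#' Each frequency is isolated with a 1 Hz-passband FIR filter (order 256,
#' Kaiser-style window, delay-compensated), then the power is estimated as
#' twice the variance of the filtered signal over a sliding window: a fixed
#' `window_ms` (offline convention) or half the period of each frequency
#' (`window_ms = NULL`, online convention), in `step_ms` steps.
#'
#' @inheritParams morlet_tfr
#' @param window_ms variance window, ms; `NULL` means half a period per
#'   frequency.
#' @param order filter order.
#' @return a `tfr`.
#' @export
variation_tfr <- function(stream, freqs, window_ms = 150, step_ms = 1,
                          order = 256L) {
  stopifnot(inherits(stream, "sample_stream"))
  fs <- stream$sampling_rate
  x <- stream$values
  n <- length(x)
  times_out <- tfr_time_grid(stream, step_ms)
  P <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    spec <- design_bandpass(f, order, fs, window = "kaiser12")
    y <- causal_fir(spec$coefficients, x)
    d <- group_delay_samples(spec)
    y <- c(y[(d + 1L):n], rep(y[n], d))       # remove the fixed delay
    w_n <- if (is.null(window_ms)) max(3L, round(fs / (2 * f)))
           else max(3L, round(window_ms / 1000 * fs))
    P[i, ] <- 2 * running_var(y, w_n)
  }
  power <- resample_rows(P, stream_times(stream), times_out)
  rownames(power) <- as.character(freqs)
  new_tfr(power, freqs,  times_out,
          if (is.null(window_ms)) "variation-half-period"
          else sprintf("variation-%g", window_ms), fs)
}

# centered running variance over a window of w samples
running_var <- function(y, w) {
  n <- length(y)
  half <- w %/% 2L
  cs <- cumsum(c(0, y)); cs2 <- cumsum(c(0, y^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  pmax((s2 - s^2 / m) / pmax(m - 1L, 1L), 0)
}

#' Detect bursts offline as peaks in the time-frequency plane
#'
#' A burst is a strict local maximum of the TFR (8-neighbourhood; on a
#' plateau the earliest time, then lowest frequency wins) that exceeds the
#' per-frequency session percentile. For each burst: the frequency span is
#' the contiguous supra-threshold frequency extent at the peak time; the
#' duration is the contiguous supra-threshold time extent at the peak
#' frequency; the inter-burst interval is the time to the previous burst
#' peak; power is reported as the fraction of the per-frequency session
#' median (FOM).
#'
#' @param tfr an un-normalized `tfr`.
#' @param percentile threshold percentile (default 98).
#' @return data.frame with one row per burst: `peak_frequency`,
#'   `peak_time_s`, `frequency_span_hz`, `duration_ms`,
#'   `inter_burst_interval_ms`, `power_fom`, `peak_power`, sorted by time.
#' @export
offline_burst_detect <- function(tfr, percentile = 98) {
  stopifnot(inherits(tfr, "tfr"), identical(tfr$normalization, "none"))
  P <- tfr$power
  nf <- nrow(P); nt <- ncol(P)
  if (nf < 2L || nt < 3L) return(empty_burst_stats())
  thr <- apply(P, 1L, function(v) percentile(v, percentile))
  med <- apply(P, 1L, stats::median)
  pad <- matrix(-Inf, nf + 2L, nt + 2L)
  pad[2:(nf + 1L), 2:(nt + 1L)] <- P
  ii <- 2:(nf + 1L); jj <- 2:(nt + 1L)
  C <- pad[ii, jj]
  # earlier neighbours (smaller time, or same time smaller frequency) must be
  # strictly smaller; later neighbours at most equal -> plateau keeps its
  # earliest-time, lowest-frequency cell
  is_peak <-
    C >  pad[ii - 1L, jj - 1L] & C >  pad[ii, jj - 1L] &
    C >  pad[ii + 1L, jj - 1L] & C >  pad[ii - 1L, jj] &
    C >= pad[ii + 1L, jj]      & C >= pad[ii - 1L, jj + 1L] &
    C >= pad[ii, jj + 1L]      & C >= pad[ii + 1L, jj + 1L]
  is_peak <- is_peak & (P > thr)
  hits <- which(is_peak, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_burst_stats())
  df <- tfr$freqs[2] - tfr$freqs[1]
  dt_ms <- (tfr$times_s[2] - tfr$times_s[1]) * 1000
  res <- lapply(seq_len(nrow(hits)), function(k) {
    i <- hits[k, 1L]; j <- hits[k, 2L]
    above_f <- P[, j] > thr
    lo <- i; while (lo > 1L && above_f[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < nf && above_f[hi + 1L]) hi <- hi + 1L
    above_t <- P[i, ] > thr[i]
    t0 <- j; while (t0 > 1L && above_t[t0 - 1L]) t0 <- t0 - 1L
    t1 <- j; while (t1 < nt && above_t[t1 + 1L]) t1 <- t1 + 1L
    data.frame(peak_frequency = tfr$freqs[i],
               peak_time_s = tfr$times_s[j],
               frequency_span_hz = (hi - lo) * df,
               duration_ms = (t1 - t0) * dt_ms,
               power_fom = P[i, j] / med[i],
               peak_power = P[i, j])
  })
  out <- do.call(rbind, res)
  out <- out[order(out$peak_time_s, out$peak_frequency), ]
  out$inter_burst_interval_ms <- c(NA, diff(out$peak_time_s) * 1000)
  rownames(out) <- NULL
  out[, c("peak_frequency", "peak_time_s", "frequency_span_hz", "duration_ms",
          "inter_burst_interval_ms", "power_fom", "peak_power")]
}

empty_burst_stats <- function() {
  data.frame(peak_frequency = numeric(0), peak_time_s = numeric(0),
             frequency_span_hz = numeric(0), duration_ms = numeric(0),
             inter_burst_interval_ms = numeric(0), power_fom = numeric(0),
             peak_power = numeric(0))
}

#' Time-locked average aligned to the last beta trough before each event
#'
#' The raw trace is bandpassed (zero-phase) in `band`; for each event time
#' the last local minimum of the filtered trace before the event is located,
#' and a raw-signal window centered on that trough is extracted. Windows are
#' averaged across events with a 95% confidence band from the t
#' distribution. With `align = FALSE` windows are centered on the event
#' times themselves.
#'
#' @param stream a `sample_stream`.
#' @param event_times_s event (e.g. reward) times, seconds.
#' @param window_s extracted window length, seconds (centered).
#' @param band alignment bandpass, Hz (default 15-30).
#' @param align align to the preceding trough (default TRUE).
#' @return list with `time_s` (offsets), `mean`, `lower`, `upper`, `n`
#'   (events used), `skipped` (events without a usable trough/window).
#' @export
time_locked_average <- function(stream, event_times_s, window_s = 0.5,
                                band = c(15, 30), align = TRUE) {
  stopifnot(inherits(stream, "sample_stream"), length(event_times_s) >= 1L)
  fs <- stream$sampling_rate
  x <- stream$values
  bw <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bw, x))
  trough_idx <- which(diff(sign(diff(y))) > 0) + 1L
  hw <- round(window_s / 2 * fs)
  segs <- list(); skipped <- 0L
  for (te in event_times_s) {
    ei <- round((te - stream$start_time) * fs) + 1L
    center <- if (align) {
      prev <- trough_idx[trough_idx < ei]
      if (length(prev) == 0L) { skipped <- skipped + 1L; next }
      prev[length(prev)]
    } else ei
    if (center - hw < 1L || center + hw > length(x)) {
      skipped <- skipped + 1L; next
    }
    segs[[length(segs) + 1L]] <- x[(center - hw):(center + hw)]
  }
  if (length(segs) == 0L)
    stop("no event had a preceding trough and a full window in range")
  M <- do.call(rbind, segs)
  n <- nrow(M)
  mu <- colMeans(M)
  if (n > 1L) {
    se <- apply(M, 2L, stats::sd) / sqrt(n)
    q <- stats::qt(0.975, n - 1L)
  } else { se <- rep(0, ncol(M)); q <- 0 }
  list(time_s = (-hw:hw) / fs, mean = mu, lower = mu - q * se,
       upper = mu + q * se, n = n, skipped = skipped)
}

#' Per-session power container
#'
#' @param power matrix of per-sample (or per-time-point) power, rows =
#'   frequencies with rownames in Hz.
#' @param mask optional `artifact_mask` or logical vector of rejected
#'   columns.
#' @return object of class `session_power`.
#' @export
session_power <- function(power, mask = NULL) {
  stopifnot(is.matrix(power), !is.null(rownames(power)))
  bad <- if (is.null(mask)) rep(FALSE, ncol(power))
         else if (inherits(mask, "artifact_mask")) mask$flags
         else as.logical(mask)
  stopifnot(length(bad) == ncol(power))
  structure(list(power = power, rejected = bad), class = "session_power")
}

#' Session-wise band power change relative to the first session
#'
#' For each session the power of each targeted frequency is averaged over
#' all artifact-free time points, normalized to the same frequency's mean in
#' session 1, averaged over the targeted frequencies, and expressed as a
#' percent change: `mean_f(mean_t P_s / mean_t P_1) * 100 - 100`. Session 1
#' is exactly 0 by construction.
#'
#' @param sessions list of `session_power`, session 1 first.
#' @param target_freqs targeted frequencies, Hz (must be rownames of every
#'   session's power matrix).
#' @return numeric vector, percent change per session.
#' @export
beta_power_change <- function(sessions, target_freqs) {
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "session_power")))
  key <- as.character(target_freqs)
  means <- vapply(sessions, function(s) {
    stopifnot(all(key %in% rownames(s$power)))
    ok <- !s$rejected
    rowMeans(s$power[key, ok, drop = FALSE])
  }, numeric(length(key)))
  means <- matrix(means, nrow = length(key))
  if (any(means[, 1L] == 0))
    stop("zero mean power in session 1 at a targeted frequency")
  colMeans(means / means[, 1L]) * 100 - 100
}

#' Training effect: reward-locked power difference-of-differences
#'
#' `(P9_pre - P9_post) - (P1_pre - P1_post)` per frequency, where `pre` /
#' `post` are mean time-frequency power in the 200 ms before / after reward
#' in the first (1) and last (9) session.
#'
#' @param pre1,post1,pre9,post9 named numeric vectors of mean power per
#'   frequency, identical names.
#' @return named numeric vector of the per-frequency effect.
#' @export
training_effect <- function(pre1, post1, pre9, post9) {
  nm <- names(pre1)
  if (is.null(nm) ||
      !identical(nm, names(post1)) || !identical(nm, names(pre9)) ||
      !identical(nm, names(post9)))
    stop("frequency axes of the four mean-power vectors do not match")
  (pre9 - post9) - (pre1 - post1)
}

#' Mean time-frequency power in epochs around events
#'
#' Averages a TFR over windows `[t - window_s, t)` (side "pre") or
#' `[t, t + window_s)` (side "post") across events, returning one mean per
#' frequency. Feeds [training_effect()].
#'
#' @param tfr a `tfr`.
#' @param event_times_s event times, seconds.
#' @param window_s epoch length (default 0.2).
#' @param side `"pre"` or `"post"`.
#' @return named numeric vector (names = frequencies).
#' @export
epoch_mean_power <- function(tfr, event_times_s, window_s = 0.2,
                             side = c("pre", "post")) {
  side <- match.arg(side)
  sel <- rep(FALSE, length(tfr$times_s))
  for (te in event_times_s) {
    w <- if (side == "pre") c(te - window_s, te) else c(te, te + window_s)
    sel <- sel | (tfr$times_s >= w[1] & tfr$times_s < w[2])
  }
  if (!any(sel)) stop("no TFR time points fall inside the requested epochs")
  out <- rowMeans(tfr$power[, sel, drop = FALSE])
  names(out) <- as.character(tfr$freqs)
  out
}

#' Per-frequency t-tests on the training effect
#'
#' Thin reporting layer: given per-epoch frequency profiles (rows = epochs,
#' columns = frequencies) for the four conditions, computes the effect of
#' [training_effect()] from the condition means and two-sample Welch t-tests
#' of the per-epoch pre-post differences (session 9 vs session 1) per
#' frequency, Bonferroni-adjusted.
#'
#' @param pre1,post1,pre9,post9 matrices (epochs x frequencies), equal
#'   colnames; pre/post row counts must match within a session.
#' @return data.frame `frequency`, `effect`, `p`, `p_bonferroni`.
#' @export
training_effect_test <- function(pre1, post1, pre9, post9) {
  nm <- colnames(pre1)
  stopifnot(!is.null(nm), identical(nm, colnames(post1)),
            identical(nm, colnames(pre9)), identical(nm, colnames(post9)),
            nrow(pre1) == nrow(post1), nrow(pre9) == nrow(post9))
  eff <- training_effect(colMeans(pre1), colMeans(post1),
                         colMeans(pre9), colMeans(post9))
  d1 <- pre1 - post1; d9 <- pre9 - post9
  p <- vapply(seq_along(nm), function(j)
    stats::t.test(d9[, j], d1[, j])$p.value, numeric(1))
  data.frame(frequency = as.numeric(nm), effect = as.numeric(eff), p = p,
             p_bonferroni = stats::p.adjust(p, "bonferroni"))
}

#' Export a TFR as a delimited matrix
#'
#' First column is the frequency; the header row carries the time axis.
#' @param tfr a `tfr`.
#' @param path output file.
#' @export
write_tfr <- function(tfr, path) {
  M <- cbind(frequency_hz = tfr$freqs, tfr$power)
  colnames(M) <- c("frequency_hz", sprintf("%.6f", tfr$times_s))
  utils::write.table(M, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
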