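# Online artifact rejection (amplitude threshold on a 2-250 Hz Butterworth-
# filtered copy of the raw trace, with +/- 500 ms dilation) and the dynamic
# per-frequency percentile threshold computed every second over the last 15 s
# of artifact-free power.

#' Detect high-amplitude artifacts in a raw recording
#'
#' The raw trace is passed through a 2nd-order (12 dB/octave) Butterworth
#' bandpass between 2 and 250 Hz to suppress slow drifts and spike-band
#' energy, then samples whose absolute value exceeds `threshold_uv` are
#' flagged together with all samples within `pad_s` seconds before and after
#' (half-open intervals `[onset - pad, offset + pad)`).
#'
#' @param stream a `sample_stream` in microvolts; sampling rate must exceed
#'   500 Hz so the 250 Hz band edge is below Nyquist.
#' @param threshold_uv amplitude threshold, microvolts (default 500).
#' @param pad_s dilation, seconds (default 0.5).
#' @param band detection bandpass edges, Hz.
#' @return object of class `artifact_mask`: list with `flags` (logical per
#'   sample), `threshold`, `pad`, `intervals` (data.frame start_s, end_s) and
#'   `sampling_rate`.
#' @export
detect_artifacts <- function(stream, threshold_uv = 500, pad_s = 0.5,
                             band = c(2, 250)) {
  stopifnot(inherits(stream, "sample_stream"))
  if (pad_s < 0) stop("pad must be nonnegative")
  fs <- stream$sampling_rate
  if (fs <= 2 * band[2]) stop("sampling rate must exceed ", 2 * band[2], " Hz")
  bw <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(bw, stream$values))
  hot <- abs(y) > threshold_uv
  pad_n <- as.integer(round(pad_s * fs))
  flags <- dilate_flags(hot, pad_n)
  structure(list(flags = flags, threshold = threshold_uv, pad = pad_s,
                 intervals = flags_to_intervals(flags, fs, stream$start_time),
                 sampling_rate = fs),
            class = "artifact_mask")
}

dilate_flags <- function(hot, pad_n) {
  if (!any(hot) || pad_n == 0L) {
    if (pad_n == 0L) return(hot)
    return(hot)
  }
  n <- length(hot)
  delta <- integer(n + 1L)
  idx <- which(hot)
  lo <- pmax(idx - pad_n, 1L)
  hi <- pmin(idx + pad_n, n)
  for (k in seq_along(idx)) {
    delta[lo[k]] <- delta[lo[k]] + 1L
    delta[hi[k] + 1L] <- delta[hi[k] + 1L] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0L
}

flags_to_intervals <- function(flags, fs, start_time = 0) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(start_s = start_time + (starts[on] - 1L) / fs,
             end_s = start_time + ends[on] / fs)
}

#' Write artifact intervals as TSV
#' @param mask an `artifact_mask`.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(format(mask$intervals, digits = 7), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dynamic per-frequency percentile threshold
#'
#' Emulates the online threshold: once per `update_s` seconds, for every
#' frequency, take the most recent `window_s` seconds' worth of
#' artifact-free power samples at or before the update time (masked spans
#' are back-filled with the most recent earlier artifact-free values, so the
#' history always spans a full window) and set the threshold to the stated
#' percentile of that history. The threshold is held constant until the next
#' update; before the first full window it is not ready (NA).
#'
#' @param power matrix of per-sample power, rows = frequencies (rownames =
#'   center frequencies in Hz).
#' @param mask optional `artifact_mask` whose flagged samples are excluded.
#' @param sampling_rate Hz.
#' @param percentile percentile in (0, 100] (default 98).
#' @param window_s history span, seconds (default 15).
#' @param update_s update interval, seconds (default 1).
#' @return object of class `threshold_state`: list with `thresholds` (matrix
#'   like `power`, NA where not ready), `history` (data.frame time_s,
#'   frequency_hz, threshold at each update), plus the parameters.
#' @export
dynamic_threshold <- function(power, mask = NULL, sampling_rate,
                              percentile = 98, window_s = 15, update_s = 1) {
  stopifnot(is.matrix(power), sampling_rate > 0, window_s > 0, update_s > 0)
  n <- ncol(power)
  good <- if (is.null(mask)) rep(TRUE, n) else !mask$flags
  stopifnot(length(good) == n)
  w_n <- as.integer(round(window_s * sampling_rate))
  upd_times <- seq(update_s, n / sampling_rate, by = update_s)
  upd_samples <- as.integer(round(upd_times * sampling_rate))
  ok <- !duplicated(upd_samples) & upd_samples >= 1L & upd_samples <= n
  upd_times <- upd_times[ok]
  upd_samples <- upd_samples[ok]
  thresholds <- matrix(NA_real_, nrow = nrow(power), ncol = n,
                       dimnames = dimnames(power))
  good_idx <- which(good)
  hist_rows <- vector("list", length(upd_samples))
  freqs <- rownames(power)
  for (j in seq_along(upd_samples)) {
    u <- upd_samples[j]
    avail <- good_idx[good_idx <= u]
    if (length(avail) >= w_n) {
      take <- avail[(length(avail) - w_n + 1L):length(avail)]
      thr <- unname(apply(power[, take, drop = FALSE], 1L,
                          function(v) percentile(v, percentile)))
    } else {
      thr <- rep(NA_real_, nrow(power))   # session start: not ready
    }
    upto <- if (j < length(upd_samples)) upd_samples[j + 1L] - 1L else n
    thresholds[, u:upto] <- thr
    hist_rows[[j]] <- data.frame(time_s = upd_times[j],
                                 frequency_hz = as.numeric(freqs),
                                 threshold = thr)
  }
  structure(list(thresholds = thresholds,
                 history = do.call(rbind, hist_rows),
                 percentile = percentile, window_s = window_s,
                 update_s = update_s, sampling_rate = sampling_rate),
            class = "threshold_state")
}

#' Write the threshold history as TSV (time, frequency, threshold)
#' @param state a `threshold_state`.
#' @param path output file.
#' @export
write_thresholds <- function(state, path) {
  utils::write.table(format(state$history, digits = 7), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
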