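# The burst decision rule: a frequency channel is "bursting" at a sample when
# its power exceeds both neighbouring frequencies and its own dynamic
# percentile threshold; contiguous runs become burst events, and events in
# the target band lasting >= 70 ms trigger rewards subject to priming,
# delivery and lockout rules.

#' Per-sample, per-frequency burst flags
#'
#' `flag(f, t)` is TRUE when the power at f exceeds the power at f - 1 and
#' f + 1 (strict: ties fail) and the threshold at f. Edge frequencies (the
#' first and last rows, which lack a neighbour) are never flagged. Samples
#' with a not-ready (NA) threshold are never flagged.
#'
#' @param power matrix of per-sample power, rows = frequencies.
#' @param thresholds a `threshold_state` or a matrix conformable with
#'   `power`.
#' @return logical matrix like `power`.
#' @export
burst_flag <- function(power, thresholds) {
  thr <- if (inherits(thresholds, "threshold_state")) thresholds$thresholds
         else thresholds
  stopifnot(is.matrix(power), all(dim(thr) == dim(power)))
  nf <- nrow(power)
  flags <- matrix(FALSE, nf, ncol(power), dimnames = dimnames(power))
  if (nf < 3L) return(flags)
  mid <- 2:(nf - 1L)
  flags[mid, ] <- power[mid, , drop = FALSE] > power[mid - 1L, , drop = FALSE] &
                  power[mid, , drop = FALSE] > power[mid + 1L, , drop = FALSE] &
                  power[mid, , drop = FALSE] > thr[mid, , drop = FALSE]
  flags[is.na(flags)] <- FALSE
  flags
}

#' Collect burst events from per-sample flags
#'
#' Maximal runs of contiguous TRUE flags in one frequency channel become
#' burst events; events whose frequency lies in the target band and whose
#' duration reaches `min_duration_ms` are reward-eligible. With
#' `band_union = TRUE` the flags of all target-band channels are OR-ed first
#' and a run may drift across adjacent frequencies (the event frequency is
#' then the channel with the highest power at the run's peak sample).
#'
#' @param flags logical matrix from [burst_flag()].
#' @param power matching power matrix (for peak power).
#' @param sampling_rate Hz.
#' @param target_band numeric length-2, inclusive band edges in Hz.
#' @param min_duration_ms minimum rewarded duration (default 70).
#' @param band_union gate duration on the union of target-band flags.
#' @param start_time stream start time, seconds.
#' @return data.frame of events: `frequency`, `onset_sample`, `onset_s`,
#'   `duration_ms`, `peak_power`, `eligible`, `eligible_at_s` (time at which
#'   the duration criterion is met, NA if ineligible), sorted by onset.
#' @export
accumulate_bursts <- function(flags, power, sampling_rate,
                              target_band = c(20, 25), min_duration_ms = 70,
                              band_union = FALSE, start_time = 0) {
  stopifnot(is.matrix(flags), all(dim(power) == dim(flags)))
  if (length(target_band) != 2L || target_band[2] < target_band[1])
    stop("target band must be a nonempty [low, high] range")
  freqs <- as.numeric(rownames(flags))
  in_band <- freqs >= target_band[1] & freqs <= target_band[2]
  if (!any(in_band)) stop("target band contains no filter-bank frequency")
  events <- list()
  runs_of <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    data.frame(start = ends - r$lengths + 1L, end = ends)[r$values, ,
                                                          drop = FALSE]
  }
  if (band_union) {
    union_flags <- colSums(flags[in_band, , drop = FALSE]) > 0L
    rr <- runs_of(union_flags)
    for (k in seq_len(nrow(rr))) {
      seg <- power[in_band, rr$start[k]:rr$end[k], drop = FALSE]
      peak <- which(seg == max(seg), arr.ind = TRUE)[1L, ]
      events[[length(events) + 1L]] <- data.frame(
        frequency = freqs[in_band][peak[1L]],
        onset_sample = rr$start[k], run_len = rr$end[k] - rr$start[k] + 1L,
        peak_power = max(seg), in_band = TRUE)
    }
    # channels outside the band still produce (ineligible) per-channel events
    rows <- which(!in_band)
  } else rows <- seq_along(freqs)
  for (i in rows) {
    rr <- runs_of(flags[i, ])
    for (k in seq_len(nrow(rr))) {
      events[[length(events) + 1L]] <- data.frame(
        frequency = freqs[i],
        onset_sample = rr$start[k], run_len = rr$end[k] - rr$start[k] + 1L,
        peak_power = max(power[i, rr$start[k]:rr$end[k]]),
        in_band = in_band[i])
    }
  }
  if (length(events) == 0L)
    return(data.frame(frequency = numeric(0), onset_sample = integer(0),
                      onset_s = numeric(0), duration_ms = numeric(0),
                      peak_power = numeric(0), eligible = logical(0),
                      eligible_at_s = numeric(0)))
  ev <- do.call(rbind, events)
  ev$onset_s <- start_time + (ev$onset_sample - 1L) / sampling_rate
  ev$duration_ms <- ev$run_len / sampling_rate * 1000
  ev$eligible <- ev$in_band & ev$duration_ms >= min_duration_ms
  ev$eligible_at_s <- ifelse(ev$eligible,
                             ev$onset_s + min_duration_ms / 1000, NA_real_)
  ev <- ev[order(ev$onset_sample, ev$frequency), ]
  rownames(ev) <- NULL
  ev[, c("frequency", "onset_sample", "onset_s", "duration_ms", "peak_power",
         "eligible", "eligible_at_s")]
}

#' Reward state machine
#'
#' Emits 5 priming rewards in the first 15 s (one every 3 s, starting at 0,
#' covering the threshold fill-in period), then one reward per eligible burst
#' event; a reward is suppressed while a previous reward is being delivered
#' and for `lockout_s` after it, and during artifact spans and for
#' `lockout_s` after an artifact. Reward times include the configured
#' processing latency.
#'
#' @param events data.frame from [accumulate_bursts()].
#' @param session_length_s session length, seconds.
#' @param mask optional `artifact_mask`.
#' @param volume_ul reward volume, microliters (default 50).
#' @param rate_ul_s delivery rate (default 50 ul/s, so delivery takes
#'   `volume_ul / rate_ul_s` seconds).
#' @param lockout_s lockout after a reward or artifact (default 1).
#' @param latency_s processing latency added to reward timestamps
#'   (default 0.002).
#' @param priming_n,priming_interval_s,priming_window_s priming schedule
#'   (defaults: 5 rewards every 3 s within the first 15 s).
#' @return data.frame of rewards: `time_s`, `volume_ul`, `lockout_until_s`,
#'   `kind` ("priming"/"burst").
#' @export
reward_controller <- function(events, session_length_s, mask = NULL,
                              volume_ul = 50, rate_ul_s = 50, lockout_s = 1,
                              latency_s = 0.002, priming_n = 5,
                              priming_interval_s = 3, priming_window_s = 15) {
  if (lockout_s < 0 || latency_s < 0 || volume_ul <= 0 || rate_ul_s <= 0)
    stop("lockout, latency, volume and rate must be nonnegative/positive")
  delivery_s <- volume_ul / rate_ul_s
  prime_t <- seq(0, by = priming_interval_s, length.out = priming_n)
  prime_t <- prime_t[prime_t < min(priming_window_s, session_length_s)]
  rewards <- data.frame(time_s = prime_t,
                        volume_ul = rep(volume_ul, length(prime_t)),
                        lockout_until_s = prime_t + delivery_s + lockout_s,
                        kind = rep("priming", length(prime_t)))
  elig <- events[!is.na(events$eligible_at_s) & events$eligible, , drop = FALSE]
  if (nrow(elig) > 0L && is.unsorted(elig$onset_s))
    elig <- elig[order(elig$onset_s), ]
  art_lock <- if (!is.null(mask) && nrow(mask$intervals) > 0L)
    data.frame(start = mask$intervals$start_s,
               end = mask$intervals$end_s + lockout_s)
  else data.frame(start = numeric(0), end = numeric(0))
  for (k in seq_len(nrow(elig))) {
    t_r <- elig$eligible_at_s[k] + latency_s
    if (t_r < priming_window_s || t_r > session_length_s) next
    if (nrow(rewards) > 0L && any(t_r < rewards$lockout_until_s &
                                  t_r >= rewards$time_s)) next
    if (nrow(art_lock) > 0L && any(t_r >= art_lock$start & t_r < art_lock$end))
      next
    rewards <- rbind(rewards, data.frame(
      time_s = t_r, volume_ul = volume_ul,
      lockout_until_s = t_r + delivery_s + lockout_s, kind = "burst"))
  }
  rownames(rewards) <- NULL
  rewards
}

#' Sham replay of a recorded reward schedule
#'
#' Re-emits a recorded reward schedule verbatim, irrespective of the current
#' signal (the sham-control condition: the subject receives the trained
#' subject's reward history).
#'
#' @param schedule_times_s recorded reward times, seconds.
#' @param volume_ul reward volume.
#' @param rate_ul_s delivery rate.
#' @param lockout_s lockout bookkeeping for the log.
#' @return data.frame in the same shape as [reward_controller()] output.
#' @export
sham_replay <- function(schedule_times_s, volume_ul = 50, rate_ul_s = 50,
                        lockout_s = 1) {
  t <- sort(as.numeric(schedule_times_s))
  data.frame(time_s = t, volume_ul = rep(volume_ul, length(t)),
             lockout_until_s = t + volume_ul / rate_ul_s + lockout_s,
             kind = rep("sham", length(t)))
}

#' Write burst events as TSV
#' @param events data.frame from [accumulate_bursts()] (optionally with a
#'   `rewarded` column).
#' @param path output file.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset_s = sprintf("%.6f", events$onset_s),
                    frequency_hz = events$frequency,
                    duration_ms = sprintf("%.3f", events$duration_ms),
                    peak_power = events$peak_power,
                    rewarded = as.integer(if ("rewarded" %in% names(events))
                      events$rewarded else events$eligible))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reward log as TSV
#' @param rewards data.frame from [reward_controller()].
#' @param path output file.
#' @export
write_rewards <- function(rewards, path) {
  out <- data.frame(time_s = sprintf("%.6f", rewards$time_s),
                    volume_ul = rewards$volume_ul, kind = rewards$kind)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
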