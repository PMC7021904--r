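# Recording I/O (CSV and a minimal EDF reader/writer), run configuration,
# and the end-to-end session emulation that ties filtering, thresholds,
# burst logic and rewards together.

#' Load a continuous recording
#'
#' CSV: comma-separated with header `time_s,amplitude_uv`; the sampling rate
#' is inferred from the time column and must be regular (jitter below 1% of
#' the sample interval). EDF: the sampling rate is read from the header and
#' the first signal (or `channel`) is returned in physical units.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param channel EDF signal index (default 1).
#' @return a `sample_stream` in microvolts.
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf"),
                           channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop("unknown recording format: .", ext))
  }
  if (format == "csv") load_recording_csv(path) else read_edf(path, channel)
}

load_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_uv") %in% names(df)))
    stop("CSV must have header time_s,amplitude_uv")
  if (nrow(df) < 2L) stop("recording too short")
  dt <- diff(df$time_s)
  step <- stats::median(dt)
  if (step <= 0) stop("nonincreasing time column")
  bad <- which(abs(dt - step) > 0.01 * step)
  if (length(bad) > 0L)
    stop("irregular sampling: time step at row ", bad[1L] + 1L,
         " deviates more than 1% from the median interval")
  sample_stream(df$amplitude_uv, 1 / step, start_time = df$time_s[1L])
}

#' Write a recording as CSV (`time_s,amplitude_uv`)
#' @param stream a `sample_stream`.
#' @param path output file.
#' @export
write_recording <- function(stream, path) {
  stopifnot(inherits(stream, "sample_stream"))
  # %.17g preserves doubles exactly, so a written trace reloads bit-for-bit
  df <- data.frame(time_s = sprintf("%.17g", stream_times(stream)),
                   amplitude_uv = sprintf("%.17g", stream$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a single-channel recording as EDF
#'
#' Minimal European Data Format writer: one signal, one data record holding
#' the whole trace, 16-bit integer samples scaled to the signal's physical
#' range. Intended for round-trip interchange of modest traces, not for
#' long archival recordings.
#'
#' @param stream a `sample_stream` (microvolts).
#' @param path output file.
#' @param label signal label.
#' @export
write_edf <- function(stream, path, label = "LFP") {
  stopifnot(inherits(stream, "sample_stream"))
  x <- stream$values
  n <- length(x)
  phys_min <- min(x); phys_max <- max(x)
  if (phys_max == phys_min) phys_max <- phys_min + 1
  dig_min <- -32768; dig_max <- 32767
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- as.integer(round((x - phys_min) / scale) + dig_min)
  record_dur <- n / stream$sampling_rate
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80), edf_field("X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 + 256, 8), edf_field("", 44),
    edf_field(1, 8), edf_field(format(record_dur, digits = 8), 8),
    edf_field(1, 4))
  sig <- paste0(
    edf_field(label, 16), edf_field("", 80), edf_field("uV", 8),
    edf_field(format(phys_min, digits = 8), 8),
    edf_field(format(phys_max, digits = 8), 8),
    edf_field(dig_min, 8), edf_field(dig_max, 8), edf_field("", 80),
    edf_field(n, 8), edf_field("", 32))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for continuous EDF: parses the ASCII header, reads the
#' 16-bit integer records of the requested signal and rescales them to
#' physical units; the sampling rate is samples-per-record divided by the
#' record duration from the header.
#'
#' @param path EDF file.
#' @param channel signal index (default 1).
#' @return a `sample_stream`.
#' @export
read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L) stop("unreadable EDF header")
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  header_bytes <- num(substr(hdr, 185, 192))
  n_records <- num(substr(hdr, 237, 244))
  record_dur <- num(substr(hdr, 245, 252))
  ns <- num(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur))
    stop("unreadable EDF header")
  if (channel > ns) stop("EDF has only ", ns, " signal(s)")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  # per-signal fields are stored field-major: all labels, then all
  # transducers, units, physical/digital ranges, prefilters, record sizes
  take <- function(name, width) {
    starts <- cumsum(c(0, c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32) * ns))
    names(starts) <- c("label", "transducer", "unit", "phys_min", "phys_max",
                       "dig_min", "dig_max", "prefilter", "n_samples",
                       "reserved", "end")
    st <- starts[[name]] + (channel - 1L) * width + 1L
    substr(sig_hdr, st, st + width - 1L)
  }
  phys_min <- num(take("phys_min", 8)); phys_max <- num(take("phys_max", 8))
  dig_min <- num(take("dig_min", 8)); dig_max <- num(take("dig_max", 8))
  spr_all <- vapply(seq_len(ns), function(ch) {
    starts <- cumsum(c(0, c(16, 80, 8, 8, 8, 8, 8, 80) * ns))
    st <- starts[length(starts)] + (ch - 1L) * 8L + 1L
    num(substr(sig_hdr, st, st + 7L))
  }, numeric(1))
  if (any(is.na(spr_all))) stop("unreadable EDF signal header")
  vals <- numeric(0)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr_all[ch], size = 2L,
                   endian = "little")
      if (ch == channel) vals <- c(vals, d)
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sample_stream(phys_min + (vals - dig_min) * scale,
                spr_all[channel] / record_dur)
}

#' Session run configuration
#'
#' Bundle of all tunable detector parameters, serializable to/from YAML.
#'
#' @param sampling_rate Hz.
#' @param band target band `[low, high]`, Hz, within the neighbour-test
#'   range 2-31 Hz.
#' @param percentile threshold percentile.
#' @param window_s threshold history window, s.
#' @param update_s threshold update interval, s.
#' @param min_duration_ms duration gate.
#' @param artifact_uv artifact amplitude threshold.
#' @param latency_ms processing latency.
#' @param seed integer seed.
#' @param mode `"train"` or `"sham"`.
#' @param sham_schedule reward-time list for sham mode.
#' @param band_union gate on the union of target-band flags.
#' @return object of class `run_config`.
#' @export
run_config <- function(sampling_rate = 976.5625, band = c(20, 25),
                       percentile = 98, window_s = 15, update_s = 1,
                       min_duration_ms = 70, artifact_uv = 500,
                       latency_ms = 2, seed = 1L,
                       mode = c("train", "sham"), sham_schedule = NULL,
                       band_union = FALSE) {
  mode <- match.arg(mode)
  stopifnot(window_s > 0, update_s > 0, min_duration_ms > 0,
            artifact_uv > 0, latency_ms >= 0)
  if (band[1] < 2 || band[2] > 31 || band[2] < band[1])
    stop("target band must lie within 2-31 Hz (both neighbours needed)")
  structure(list(sampling_rate = sampling_rate, band = band,
                 percentile = percentile, window_s = window_s,
                 update_s = update_s, min_duration_ms = min_duration_ms,
                 artifact_uv = artifact_uv, latency_ms = latency_ms,
                 seed = as.integer(seed), mode = mode,
                 sham_schedule = sham_schedule, band_union = band_union),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(raw[setdiff(names(raw), "mode")],
                        list(mode = raw$mode)))
}

#' Emulate a full closed-loop session
#'
#' Runs the complete chain on a recorded or synthetic stream: filter bank,
#' extrema power latching, artifact detection, dynamic percentile
#' thresholds, neighbour-frequency burst flags, event accumulation and the
#' reward controller (or sham replay). Deterministic given (config, stream).
#'
#' @param config a `run_config`.
#' @param stream a `sample_stream` (must be longer than the filter order).
#' @param bank optional prebuilt `filter_bank`.
#' @return object of class `session_result`: list with `events`, `rewards`,
#'   `thresholds` (a `threshold_state`), `mask`, `power`, and `report` (a
#'   list of summary counts: bursts, eligible bursts, rewards,
#'   rejected-sample fraction, mean band power).
#' @export
run_session <- function(config, stream, bank = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(stream, "sample_stream"))
  if (length(stream$values) == 0L) stop("empty stream")
  if (is.null(bank)) bank <- build_bank(config$sampling_rate)
  if (config$band[1] < min(bank$centers) + 1 ||
      config$band[2] > max(bank$centers) - 1)
    stop("target band outside the filter bank's neighbour-test range")
  pipe <- run_pipeline(stream, bank)
  mask <- detect_artifacts(stream, threshold_uv = config$artifact_uv)
  thr <- dynamic_threshold(pipe$power, mask, config$sampling_rate,
                           percentile = config$percentile,
                           window_s = config$window_s,
                           update_s = config$update_s)
  flags <- burst_flag(pipe$power, thr)
  events <- accumulate_bursts(flags, pipe$power, config$sampling_rate,
                              target_band = config$band,
                              min_duration_ms = config$min_duration_ms,
                              band_union = config$band_union,
                              start_time = stream$start_time)
  session_len <- length(stream$values) / config$sampling_rate
  rewards <- if (config$mode == "sham") {
    if (is.null(config$sham_schedule))
      stop("sham mode requires a recorded reward schedule")
    sham_replay(config$sham_schedule)
  } else {
    reward_controller(events, session_len, mask,
                      latency_s = config$latency_ms / 1000)
  }
  events$rewarded <- FALSE
  if (config$mode == "train") {
    burst_rewards <- rewards$time_s[rewards$kind == "burst"]
    lat <- config$latency_ms / 1000
    events$rewarded <- events$eligible & !is.na(events$eligible_at_s) &
      (events$eligible_at_s + lat) %in% burst_rewards
  }
  in_band <- as.numeric(rownames(pipe$power)) >= config$band[1] &
             as.numeric(rownames(pipe$power)) <= config$band[2]
  report <- list(
    n_samples = length(stream$values),
    session_length_s = session_len,
    n_bursts = nrow(events),
    n_eligible = sum(events$eligible),
    n_rewards = nrow(rewards),
    n_priming = sum(rewards$kind == "priming"),
    rejected_fraction = mean(mask$flags),
    mean_band_power = mean(pipe$power[in_band, !mask$flags, drop = FALSE]))
  structure(list(events = events, rewards = rewards, thresholds = thr,
                 mask = mask, power = pipe$power, config = config,
                 report = report),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<session_result> %.1f s: %d bursts (%d eligible), ",
                     "%d rewards, %.3f%% samples rejected\n"),
              r$session_length_s, r$n_bursts, r$n_eligible, r$n_rewards,
              100 * r$rejected_fraction))
  invisible(x)
}

#' Write session outputs (events, rewards, thresholds TSV + JSON report)
#'
#' @param result a `session_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_session_outputs <- function(result, dir) {
  stopifnot(inherits(result, "session_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.tsv"),
             rewards = file.path(dir, "rewards.tsv"),
             thresholds = file.path(dir, "thresholds.tsv"),
             mask = file.path(dir, "artifacts.tsv"),
             report = file.path(dir, "report.json"))
  write_events(result$events, paths["events"])
  write_rewards(result$rewards, paths["rewards"])
  write_thresholds(result$thresholds, paths["thresholds"])
  write_mask(result$mask, paths["mask"])
  jsonlite::write_json(result$report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
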