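flag_oracle <- function(P, thr) {
  # literal three-condition rule, looped
  nf <- nrow(P); nt <- ncol(P)
  out <- matrix(FALSE, nf, nt)
  for (f in 2:(nf - 1L)) {
    for (t in seq_len(nt)) {
      out[f, t] <- P[f, t] > P[f - 1L, t] && P[f, t] > P[f + 1L, t] &&
        P[f, t] > thr[f, t]
    }
  }
  out
}

test_that("burst flag needs a neighbour peak and a threshold crossing", {
  P <- matrix(c(1, 5, 2), 3, 1, dimnames = list(c("19", "20", "21"), NULL))
  thr <- matrix(3, 3, 1)
  expect_true(burst_flag(P, thr)[2, 1])
  P2 <- P; P2[1, 1] <- 6
  expect_false(burst_flag(P2, thr)[2, 1])
  # ties fail the strict inequality
  P3 <- P; P3[3, 1] <- 5
  expect_false(burst_flag(P3, thr)[2, 1])
  # threshold itself must be exceeded strictly
  thr5 <- matrix(5, 3, 1)
  expect_false(burst_flag(P, thr5)[2, 1])
  # not-ready thresholds never flag
  expect_false(burst_flag(P, matrix(NA_real_, 3, 1))[2, 1])
})

test_that("edge frequencies without both neighbours never flag", {
  set.seed(1)
  P <- matrix(stats::rexp(32 * 50), 32, 50,
              dimnames = list(as.character(1:32), NULL))
  fl <- burst_flag(P, matrix(0, 32, 50))
  expect_false(any(fl[1, ]))
  expect_false(any(fl[32, ]))
})

test_that("burst flags equal the exhaustive three-condition oracle", {
  set.seed(99)
  P <- matrix(stats::runif(10 * 1000), 10, 1000,
              dimnames = list(as.character(15:24), NULL))
  thr <- matrix(stats::runif(10 * 1000), 10, 1000)
  expect_identical(unname(burst_flag(P, thr)), flag_oracle(P, thr))
})

test_that("contiguous runs become events, gated at 70 ms in band", {
  fs <- 1000
  nf <- c("21", "22", "23")
  mkflags <- function(idx) {
    fl <- matrix(FALSE, 3, 1000, dimnames = list(nf, NULL))
    fl[2, idx] <- TRUE
    fl
  }
  P <- matrix(1, 3, 1000, dimnames = list(nf, NULL))
  # 80 ms run: one eligible event
  ev <- accumulate_bursts(mkflags(101:180), P, fs, target_band = c(20, 25))
  expect_equal(nrow(ev), 1L)
  expect_true(ev$eligible)
  expect_equal(ev$duration_ms, 80)
  expect_equal(ev$frequency, 22)
  # 60 ms run: recorded but ineligible
  ev2 <- accumulate_bursts(mkflags(101:160), P, fs, target_band = c(20, 25))
  expect_false(ev2$eligible)
  # two 40 ms runs separated by one false sample: two events, neither eligible
  ev3 <- accumulate_bursts(mkflags(c(101:140, 142:181)), P, fs,
                           target_band = c(20, 25))
  expect_equal(nrow(ev3), 2L)
  expect_false(any(ev3$eligible))
  expect_error(accumulate_bursts(mkflags(1:10), P, fs,
                                 target_band = c(25, 20)), "range")
})

test_that("band_union merges a run drifting across adjacent frequencies", {
  fs <- 1000
  nf <- c("21", "22", "23")
  fl <- matrix(FALSE, 3, 1000, dimnames = list(nf, NULL))
  fl[2, 101:140] <- TRUE   # 40 ms at 22
  fl[3, 141:180] <- TRUE   # then 40 ms at 23
  P <- matrix(1, 3, 1000, dimnames = list(nf, NULL))
  P[3, 150] <- 9
  per_channel <- accumulate_bursts(fl, P, fs, target_band = c(20, 25))
  expect_false(any(per_channel$eligible))
  merged <- accumulate_bursts(fl, P, fs, target_band = c(20, 25),
                              band_union = TRUE)
  expect_equal(sum(merged$eligible), 1L)
  expect_equal(merged$frequency[merged$eligible], 23)  # strongest channel
  expect_equal(merged$duration_ms[merged$eligible], 80)
})

test_that("reward controller: priming, lockout and artifact suppression", {
  no_events <- accumulate_bursts(
    matrix(FALSE, 3, 100, dimnames = list(c("21", "22", "23"), NULL)),
    matrix(1, 3, 100), 1000, target_band = c(20, 25))
  rw <- reward_controller(no_events, session_length_s = 60)
  expect_equal(nrow(rw), 5L)
  expect_equal(rw$time_s, c(0, 3, 6, 9, 12))
  expect_true(all(rw$kind == "priming"))

  ev <- data.frame(frequency = 22, onset_sample = 1,
                   onset_s = c(20, 20.2), duration_ms = 80, peak_power = 1,
                   eligible = TRUE, eligible_at_s = c(20.07, 20.27))
  rw2 <- reward_controller(ev, session_length_s = 60)
  expect_equal(sum(rw2$kind == "burst"), 1L)  # second falls in lockout
  # an event inside an artifact-dilated span is suppressed
  mask <- structure(list(flags = logical(0),
                         intervals = data.frame(start_s = 19.5, end_s = 21)),
                    class = "artifact_mask")
  rw3 <- reward_controller(ev, session_length_s = 60, mask = mask)
  expect_equal(sum(rw3$kind == "burst"), 0L)
  expect_error(reward_controller(ev, 60, lockout_s = -1), "nonnegative")
})

test_that("sham replay reproduces a recorded schedule exactly", {
  sched <- c(0, 3, 6, 9, 12, 17.25, 23.5, 41.113)
  rw <- sham_replay(sched)
  expect_identical(rw$time_s, sched)
  expect_true(all(rw$kind == "sham"))
})

test_that("strong planted bursts yield onset-accurate eligible events", {
  # long-envelope bursts well above the noise floor, spaced so the
  # percentile threshold stays noise-dominated (a burst's supra-threshold
  # run is ~2% of the spacing); onset recovered within the group delay plus
  # one period
  onsets <- seq(4, 60, by = 8)
  spec <- surrogate_spec(duration = 66,
                         bursts = data.frame(frequency = 22,
                                             center_time = onsets,
                                             sigma = 0.1, amplitude = 2),
                         pink_amplitude = 0.75, white_amplitude = 0.15,
                         seed = 31L)
  syn <- synthesize(spec)
  noise_rms <- sqrt(mean(synthesize(surrogate_spec(
    duration = 66, pink_amplitude = 0.75, white_amplitude = 0.15,
    seed = 31L))$stream$values^2))
  expect_gte(2, 2 * noise_rms)   # planted amplitude is >= 2x noise RMS
  ev <- lfpburst:::detect_bursts_static(syn$stream, the_bank(),
                                        target_band = c(20, 25),
                                        min_duration_ms = 70)
  gd <- 128 / FS
  hit <- vapply(seq_len(nrow(syn$truth)), function(k) {
    tr <- syn$truth[k, ]
    slack <- gd + 1 / tr$frequency
    cand <- ev[ev$eligible &
               ev$onset_s >= tr$onset_s - slack &
               ev$onset_s <= tr$onset_s + tr$duration_s + slack, ]
    nrow(cand) > 0L
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  # no events at the bank's edge frequencies, ever
  expect_false(any(ev$frequency %in% c(1, 32)))
})
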