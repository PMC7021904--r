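test_that("channel gains on a pure tone match the designed responses", {
  st <- tone_stream(20, amplitude = 3, duration = 4)
  bank <- the_bank()
  filt <- stream_filter(bank, st)
  ss <- steady_cols(st, 2, 3.5)
  # unity gain at the matched channel
  expect_equal(max(filt["20", ss]), 3, tolerance = 5e-3)
  # attenuation at a distant channel, bounded by the designed response
  h10 <- magnitude_response(bank$filters[["10"]], 20)
  expect_lt(h10, 0.05)
  expect_lt(max(abs(filt["10", ss])), 0.05 * 3)
})

test_that("chunked streaming equals whole-signal filtering bit for bit", {
  st <- tone_stream(17, duration = 2)
  bank <- build_bank(centers = c(16, 17, 18))
  batch <- stream_filter(bank, st)
  for (cs in c(64L, 100L, 997L)) {
    expect_identical(stream_filter(bank, st, chunk_size = cs), batch)
  }
  expect_error(stream_filter(bank, sample_stream(1:10, FS)), "shorter")
})

test_that("turning points: counts, amplitudes, plateaus and alternation", {
  st <- tone_stream(20, amplitude = 3, duration = 4)
  x <- st$values
  ev <- detect_turning_points(x)
  one_s <- ev[ev$index > FS & ev$index <= 2 * FS, ]
  expect_equal(nrow(one_s), 40, tolerance = 0.026)  # 2f per second, +/- 1
  expect_equal(abs(one_s$amplitude), rep(3, nrow(one_s)), tolerance = 0.01)
  expect_true(all(one_s$detect_index > one_s$index))
  # strict alternation
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  # monotone ramp: no extrema
  expect_identical(nrow(detect_turning_points(seq_len(100))), 0L)
  # plateau: the extremum is the plateau's first sample, detected after it
  xp <- c(0, 1, 2, 2, 2, 1, 0)
  evp <- detect_turning_points(xp)
  expect_equal(evp$index, 3L)
  expect_equal(evp$detect_index, 6L)
  expect_equal(evp$kind, "peak")
})

test_that("alternation holds on random walks (property)", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- cumsum(stats::rnorm(200))
    ev <- detect_turning_points(x)
    if (nrow(ev) > 1L) {
      expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
      # every peak amplitude exceeds its adjacent trough amplitudes
      for (i in seq_len(nrow(ev) - 1L)) {
        a <- ev$amplitude[i]; b <- ev$amplitude[i + 1L]
        if (ev$kind[i] == "peak") expect_gt(a, b) else expect_lt(a, b)
      }
    }
  }
})

test_that("power latching holds the squared extremum at half-period steps", {
  st <- tone_stream(20, amplitude = 2, duration = 4)
  filt <- stream_filter(the_bank(), st)
  ev <- detect_turning_points(filt["20", ])
  track <- latch_power(ev, ncol(filt), frequency = 20)
  ss <- steady_cols(st, 2, 3.5)
  expect_equal(mean(track$values[ss]), 4, tolerance = 0.02)
  # update interval ~ half the period (25.6 ms at 20 Hz): +/- 2 samples
  upd <- track$update_indices
  upd <- upd[upd %in% ss]
  expect_equal(median(diff(upd)), FS / 40, tolerance = 2 / (FS / 40))
  # before any extremum the power is zero
  expect_identical(latch_power(ev[0, ], 100)$values, numeric(100))
  # stepwise: value changes only at update indices
  changes <- which(diff(track$values) != 0) + 1L
  expect_true(all(changes %in% track$update_indices))
  expect_error(latch_power(ev[c(2, 1), ], 100), "sorted")
})

test_that("a latched track tracks an amplitude step within a half period", {
  fs <- FS
  t <- (0:(6 * fs)) / fs
  amp <- ifelse(t < 3, 1, 2)
  st <- sample_stream(amp * sin(2 * pi * 20 * t), fs)
  bank <- build_bank(centers = c(19, 20, 21))
  filt <- stream_filter(bank, st)
  ev <- detect_turning_points(filt["20", ])
  track <- latch_power(ev, ncol(filt))
  # the step reaches the filter output after the group delay; allow the
  # filter's own settling (~ its impulse-response length) plus half a period
  settle <- (128 + 257) / fs + 1 / 40
  after <- round((3 + settle) * fs):round(5.5 * fs)
  expect_true(all(track$values[after] > 4 * 0.9))
})

test_that("power converges to the squared amplitude after twice the delay", {
  st <- tone_stream(24, amplitude = 1.5, duration = 2)
  bank <- build_bank(centers = c(23, 24, 25))
  pipe <- run_pipeline(st, bank)
  from <- 2 * 128 + round(FS / 24)  # two delays plus one period of latching
  expect_equal(mean(pipe$power["24", from:(2 * FS)]), 1.5^2,
               tolerance = 0.05)
})

test_that("a planted burst elevates its channel at the group delay", {
  spec <- surrogate_spec(duration = 6,
                         bursts = data.frame(frequency = 20, center_time = 3,
                                             sigma = 0.05, amplitude = 1),
                         pink_amplitude = 0, white_amplitude = 0)
  syn <- synthesize(spec)
  pipe <- run_pipeline(syn$stream, build_bank(centers = 19:21))
  peak_at <- which.max(pipe$power["20", ]) / FS
  expect_equal(peak_at, 3 + 128 / FS, tolerance = (1 / 20) / (3 + 128 / FS))
})

test_that("phase-reset delay follows the ceiling formula", {
  # 20 Hz, d = 128 samples at 976.5625 Hz: ceil(d/T)*T - d = 0.018928 s
  expect_equal(phase_reset_delay(20, 128 / FS), 3 * 0.05 - 128 / FS,
               tolerance = 1e-12)
  # d an exact multiple of the period
  expect_equal(phase_reset_delay(20, 0.15), 0)
  expect_error(phase_reset_delay(-1, 0.1), "positive")
})

test_that("sawtooth phase tracks a pure tone within 0.2 rad", {
  st <- tone_stream(20, amplitude = 3, duration = 8)
  bank <- build_bank(centers = 19:21)
  filt <- stream_filter(bank, st)
  ev <- detect_turning_points(filt["20", ])
  ph <- estimate_phase(ev, 20, FS, 128 / FS, ncol(filt))
  ss <- steady_cols(st, 4, 7)
  t <- (ss - 1) / FS
  true_ph <- (2 * pi * 20 * t - pi / 2) %% (2 * pi)  # peak of sin at phase 0
  circ_err <- Arg(exp(1i * (ph[ss] - true_ph)))
  expect_lt(mean(abs(circ_err)), 0.2)
})
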