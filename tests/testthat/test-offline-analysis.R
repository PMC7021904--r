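test_that("Morlet TFR localizes tones and scales quadratically", {
  st <- tone_stream(20, amplitude = 1, duration = 4)
  tfr <- morlet_tfr(st, 15:25)
  ss <- which(tfr$times_s > 1 & tfr$times_s < 3)
  argmax <- apply(tfr$power[, ss], 2L, function(v) tfr$freqs[which.max(v)])
  expect_true(all(argmax == 20))
  st2 <- tone_stream(20, amplitude = 2, duration = 4)
  tfr2 <- morlet_tfr(st2, 15:25)
  expect_equal(unname(tfr2$power[, ss] / tfr$power[, ss]),
               matrix(4, nrow(tfr$power), length(ss)), tolerance = 1e-6)
  expect_error(morlet_tfr(st, c(20, 600)), "Nyquist")
})

test_that("kernel convolution equals a direct convolution oracle", {
  set.seed(4)
  x <- stats::rnorm(400)
  w <- lfpburst:::morlet_kernel(20, FS, 7)
  y <- lfpburst:::kernel_conv(x, w)
  mid <- (length(w) + 1L) / 2L
  direct <- vapply(c(50, 200, 350), function(n) {
    acc <- 0 + 0i
    for (i in seq_along(x)) {
      j <- n - i + mid
      if (j >= 1L && j <= length(w)) acc <- acc + x[i] * w[j]
    }
    acc
  }, complex(1))
  expect_equal(y[c(50, 200, 350)], direct, tolerance = 1e-9)
})

test_that("sliding-window DFT power matches a literal windowed DFT", {
  set.seed(8)
  st <- sample_stream(stats::rnorm(3000), FS)
  tfr <- fft_tfr(st, 18:22, window_ms = 250)
  L <- round(0.25 * FS); if (L %% 2L == 0L) L <- L + 1L
  env <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  n0 <- 1500   # sample index; output grid is at 1 ms steps from time 0
  t_out <- (n0 - 1) / FS
  k <- seq(-(L - 1L) / 2L, (L - 1L) / 2L)
  for (f in c(18, 20, 22)) {
    lit <- abs(sum(env * st$values[n0 + k] *
                     exp(-2i * pi * f * k / FS))) * 2 / sum(env)
    grid_i <- which.min(abs(tfr$times_s - t_out))
    expect_equal(unname(tfr$power[as.character(f), grid_i]), lit^2,
                 tolerance = 1e-2)
  }
})

test_that("a wavelet smears a planted burst at least to its envelope width", {
  spec <- surrogate_spec(duration = 4,
                         bursts = data.frame(frequency = 20, center_time = 2,
                                             sigma = 0.04, amplitude = 1),
                         pink_amplitude = 0, white_amplitude = 0)
  syn <- synthesize(spec)
  tfr <- morlet_tfr(syn$stream, 15:25)
  row <- tfr$power["20", ]
  half <- row > max(row) / 2
  fwhm_ms <- sum(half) * (tfr$times_s[2] - tfr$times_s[1]) * 1000
  env_fwhm_ms <- 2 * sqrt(2 * log(2)) * 0.04 * 1000   # ~94 ms
  expect_gte(fwhm_ms, env_fwhm_ms)
})

test_that("offline burst detection recovers a planted burst", {
  spec <- surrogate_spec(duration = 10,
                         bursts = data.frame(frequency = 20, center_time = 5,
                                             sigma = 0.04, amplitude = 1),
                         pink_amplitude = 0.5, white_amplitude = 0.1,
                         seed = 13L)
  syn <- synthesize(spec)
  tfr <- morlet_tfr(syn$stream, 10:30)
  bursts <- offline_burst_detect(tfr)
  near <- bursts[abs(bursts$peak_time_s - 5) < 0.15, ]
  main <- near[which.max(near$peak_power), ]
  expect_equal(nrow(near[near$peak_power > 0.5 * main$peak_power, ]), 1L)
  expect_lte(abs(main$peak_frequency - 20), 1)
  # supra-threshold duration of a strong sigma = 0.04 burst reaches 70 ms
  expect_gte(main$duration_ms, 70)
  # FOM exceeds 1 by construction (peak > 98th percentile > median)
  expect_true(all(bursts$power_fom > 1))
})

test_that("degenerate TFRs yield no bursts", {
  flat <- lfpburst:::new_tfr(matrix(1, 5, 100), 18:22,
                             seq(0, 0.099, by = 0.001), "morlet-7", 1000)
  expect_identical(nrow(offline_burst_detect(flat)), 0L)
  zero <- lfpburst:::new_tfr(matrix(0, 5, 100), 18:22,
                             seq(0, 0.099, by = 0.001), "morlet-7", 1000)
  expect_identical(nrow(offline_burst_detect(zero)), 0L)
})

test_that("burst statistics match hand-computed values on a built TFR", {
  # one clean pyramid peak: span/duration/FOM computable by hand
  P <- matrix(0.1, 5, 200, dimnames = list(as.character(18:22), NULL))
  P[3, 96:104] <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  P[2, 100] <- 3; P[4, 100] <- 3
  tfr <- lfpburst:::new_tfr(P, 18:22, seq(0, by = 0.001, length.out = 200),
                            "morlet-7", 1000)
  b <- offline_burst_detect(tfr, percentile = 98)
  expect_equal(nrow(b), 1L)
  expect_equal(b$peak_frequency, 20)
  expect_equal(b$peak_time_s, 0.099)
  thr20 <- percentile_oracle(P[3, ], 98)
  expect_equal(b$duration_ms, sum(P[3, ] > thr20) - 1)
  expect_equal(b$power_fom, 5 / stats::median(P[3, ]))
})

test_that("time-locked averaging: coherent vs incoherent alignment", {
  onsets <- seq(2, 32, by = 2)
  clean <- synthesize(surrogate_spec(
    duration = 34,
    bursts = data.frame(frequency = 20, center_time = onsets, sigma = 0.04,
                        amplitude = 1),
    pink_amplitude = 0, white_amplitude = 0))
  tla <- time_locked_average(clean$stream, onsets + 0.1, window_s = 0.3)
  single <- make_burst(20, 1, 0.04, 1, FS, 2)
  expect_equal(max(abs(tla$mean)), max(abs(single)), tolerance = 0.02)
  expect_equal(tla$n, length(onsets))

  # random-phase bursts, no alignment: incoherent averaging shrinks ~1/sqrt(n)
  set.seed(21)
  phases <- stats::runif(length(onsets), 0, 2 * pi)
  t <- (seq_len(round(34 * FS)) - 1) / FS
  x <- 0
  for (k in seq_along(onsets)) {
    x <- x + sin(2 * pi * 20 * (t - onsets[k]) + phases[k]) *
      exp(-(t - onsets[k])^2 / (2 * 0.04^2))
  }
  st <- sample_stream(x, FS)
  unaligned <- time_locked_average(st, onsets + 0.1, window_s = 0.3,
                                   align = FALSE)
  expect_lt(max(abs(unaligned$mean)), max(abs(single)) / 2)
  # trough alignment restores an apparent sustained oscillation at ~20 Hz
  aligned <- time_locked_average(st, onsets + 0.1, window_s = 0.3)
  expect_gt(max(abs(aligned$mean)), max(abs(unaligned$mean)))
  sp <- Mod(stats::fft(aligned$mean))
  fgrid <- (seq_along(sp) - 1) * FS / length(sp)
  in_range <- fgrid > 5 & fgrid < 100
  peak_f <- fgrid[in_range][which.max(sp[in_range])]
  expect_lte(abs(peak_f - 20), 2)
})

test_that("band power change follows the session-normalized mean", {
  mk <- function(mult, n = 50) {
    session_power(matrix(mult * (1:6), 6, n,
                         dimnames = list(as.character(20:25), NULL)))
  }
  expect_equal(beta_power_change(list(mk(1), mk(1), mk(1)), 20:25),
               c(0, 0, 0))
  expect_equal(beta_power_change(list(mk(1), mk(2)), 20:25), c(0, 100))
  # invariant to uniform rescaling of all sessions
  expect_equal(beta_power_change(list(mk(3), mk(6)), 20:25), c(0, 100))
  # artifact columns are excluded from the means
  s2 <- mk(2)
  s2$power[, 1:10] <- 1000
  s2$rejected[1:10] <- TRUE
  expect_equal(beta_power_change(list(mk(1), s2), 20:25), c(0, 100))
  zero <- session_power(matrix(0, 6, 10,
                               dimnames = list(as.character(20:25), NULL)))
  expect_error(beta_power_change(list(zero, mk(1)), 20:25), "zero mean")
})

test_that("power change equals a literal double-loop transcription", {
  set.seed(17)
  freqs <- as.character(20:25)
  sessions <- lapply(1:4, function(s) {
    session_power(matrix(stats::rexp(6 * 40) + 0.5, 6, 40,
                         dimnames = list(freqs, NULL)))
  })
  got <- beta_power_change(sessions, 20:25)
  # literal transcription: sum over f of (mean_t P_s / mean_t P_1) / n
  oracle <- vapply(seq_along(sessions), function(s) {
    acc <- 0
    for (f in freqs) {
      Ps <- sessions[[s]]$power[f, ]
      P1 <- sessions[[1]]$power[f, ]
      acc <- acc + (sum(Ps) / length(Ps)) / (sum(P1) / length(P1))
    }
    acc / length(freqs) * 100 - 100
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("training effect is the difference of pre/post differences", {
  f <- as.character(5:10)
  x <- stats::setNames(rep(1, 6), f)
  expect_equal(training_effect(x, x, x, x), stats::setNames(rep(0, 6), f))
  p9 <- x + 2
  expect_equal(unname(training_effect(x, x, p9, x)), rep(2, 6))
  expect_error(training_effect(x, x, p9, stats::setNames(rep(1, 6),
                                                         as.character(6:11))),
               "match")
})

test_that("planted pre-reward bursts produce a band-limited effect", {
  freqs <- c(20:25, seq(40, 100, by = 10))
  rewards <- seq(3, 27, by = 3)
  base <- function(seed) surrogate_spec(
    duration = 30, pink_amplitude = 0.5, white_amplitude = 0.1, seed = seed)
  burst_spec <- surrogate_spec(
    duration = 30,
    bursts = data.frame(frequency = 22, center_time = rewards - 0.1,
                        sigma = 0.04, amplitude = 1.5),
    pink_amplitude = 0.5, white_amplitude = 0.1, seed = 101L)
  s1 <- synthesize(base(100L))       # session 1: no planted bursts
  s9 <- synthesize(burst_spec)       # session 9: bursts just before rewards
  tfr1 <- morlet_tfr(s1$stream, freqs)
  tfr9 <- morlet_tfr(s9$stream, freqs)
  eff <- training_effect(
    epoch_mean_power(tfr1, rewards, side = "pre"),
    epoch_mean_power(tfr1, rewards, side = "post"),
    epoch_mean_power(tfr9, rewards, side = "pre"),
    epoch_mean_power(tfr9, rewards, side = "post"))
  beta <- eff[as.character(20:25)]
  high <- eff[as.character(seq(40, 100, by = 10))]
  expect_gt(max(beta), 10 * max(abs(high)))
  expect_gt(eff[["22"]], 0)
})

test_that("training effect test reports Bonferroni-adjusted p-values", {
  set.seed(33)
  f <- as.character(18:22)
  mk <- function(shift = 0) {
    m <- matrix(stats::rnorm(20 * 5), 20, 5, dimnames = list(NULL, f))
    m[, 3] <- m[, 3] + shift
    m
  }
  res <- training_effect_test(mk(), mk(), mk(3), mk())
  expect_equal(res$frequency, 18:22)
  expect_true(all(res$p_bonferroni >= res$p))
  expect_lt(res$p_bonferroni[3], 0.01)
  expect_gt(res$effect[3], 2)
})

test_that("resource equation gives the minimal group size", {
  expect_identical(resource_equation_n(9), 3L)
  expect_identical(resource_equation_n(2), 11L)
  expect_error(resource_equation_n(1))
})
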