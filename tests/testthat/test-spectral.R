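test_that("Welch PSD localizes tones and satisfies Parseval", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  psd <- welch_psd(tone, window_s = 2, fs = fs)
  expect_lt(abs(psd$freqs[which.max(psd$power[, 1])] - 10), 0.5 + 1e-9)

  expect_true(all(welch_psd(numeric(5 * fs), fs = fs)$power == 0))

  set.seed(2)
  x <- rnorm(60 * fs, sd = 3)
  psd <- welch_psd(x, window_s = 2, fs = fs)
  integrated <- sum(psd$power[, 1]) * diff(psd$freqs[1:2])
  expect_lt(abs(integrated - stats::var(x)) / stats::var(x), 0.05)

  expect_error(welch_psd(rnorm(100), window_s = 2, fs = 250), "shorter")
})

test_that("alpha peak selection needs a prominent bump above 1/f", {
  f <- seq(0.5, 40, by = 0.25)
  bg <- 10 / f
  bump9 <- 30 * exp(-(f - 9)^2 / 0.5)
  ab <- find_alpha_peak(power_spectrum(f, bg + bump9))
  expect_true(ab$peak_found)
  expect_equal(ab$f_peak, 9)
  expect_equal(ab$band, c(8, 10))

  # pure 1/f: no peak (prerequisite-peak principle)
  none <- find_alpha_peak(power_spectrum(f, bg))
  expect_false(none$peak_found)
  expect_true(is.na(none$f_peak))

  # two bumps, the 10 Hz one more prominent
  two <- find_alpha_peak(power_spectrum(f, bg + 8 * exp(-(f - 8)^2 / 0.5) +
                                          30 * exp(-(f - 10)^2 / 0.5)))
  expect_equal(two$f_peak, 10)

  expect_error(find_alpha_peak(power_spectrum(f, bg), search_band = c(50, 60)),
               "empty")
})

test_that("bandpass meets its frequency-response contract", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  rec9 <- recording(matrix(sin(2 * pi * 9 * t), 1), fs, reference = "vertex")
  nb <- bandpass(rec9, c(8, 10))
  interior <- (3 * fs):(length(t) - 3 * fs)
  gain9 <- max(abs(nb$data[1, interior]))
  expect_gt(gain9, 0.9)
  expect_lt(gain9, 1.1)

  for (f_stop in c(4, 20)) { # one octave outside the band on each side
    rec <- recording(matrix(sin(2 * pi * f_stop * t), 1), fs,
                     reference = "vertex")
    g <- max(abs(bandpass(rec, c(8, 10))$data[1, interior]))
    expect_lt(g, 0.01)
  }

  z <- bandpass(recording(matrix(0, 1, 5 * fs), fs, reference = "vertex"),
                c(8, 10))
  expect_true(all(z$data == 0))

  expect_error(bandpass(rec9, c(0, 10)), "Nyquist")
  expect_error(bandpass(rec9, c(120, 126)), "Nyquist")

  # idempotence on the passband: filtering twice changes little
  twice <- bandpass(nb, c(8, 10))
  expect_lt(max(abs(twice$data[1, interior] - nb$data[1, interior])), 0.02)
})

test_that("analytic envelope recovers amplitude and ignores carrier phase", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  rec <- recording(matrix(5 * cos(2 * pi * 9 * t), 1), fs,
                   reference = "vertex")
  env <- suppressWarnings(analytic_envelope(rec))
  interior <- fs:(length(t) - fs)
  expect_lt(max(abs(env$env[1, interior] - 5)), 1e-6)

  z <- suppressWarnings(analytic_envelope(
    recording(matrix(0, 1, 100), fs, reference = "vertex")))
  expect_true(all(z$env == 0))

  # amplitude-modulated carrier: envelope matches the modulation
  A <- gen_envelope(2, 60, fs, seed = 4)
  tt <- (seq_along(A) - 1) / fs
  x <- recording(matrix(A * cos(2 * pi * 9 * tt), 1), fs,
                 reference = "vertex")
  e <- suppressWarnings(analytic_envelope(x))
  i2 <- (2 * fs):(60 * fs - 2 * fs)
  expect_gte(stats::cor(e$env[1, i2], A[i2]), 0.99)

  # carrier phase invariance: for strictly band-limited modulation (integer
  # cycle counts, so the DFT is exact) cos and sin carriers give identical
  # envelopes to near machine precision
  A_bl <- 2 + 0.5 * cos(2 * pi * 0.3 * tt) + 0.3 * sin(2 * pi * 0.5 * tt)
  bc <- recording(matrix(A_bl * cos(2 * pi * 9 * tt), 1), fs,
                  reference = "vertex")
  bs <- recording(matrix(A_bl * sin(2 * pi * 9 * tt), 1), fs,
                  reference = "vertex")
  eb_c <- suppressWarnings(analytic_envelope(bc))
  eb_s <- suppressWarnings(analytic_envelope(bs))
  rel <- abs(eb_s$env[1, i2] - eb_c$env[1, i2]) / max(eb_c$env[1, i2])
  expect_lt(max(rel), 1e-6)

  # unfiltered input carries a provenance warning, not an error
  expect_warning(analytic_envelope(rec), "provenance")
})

test_that("simulator round trip: the configured peak is recovered at scalp and depth", {
  hm <- head_model(n_sensors = 16)
  cfg <- sim_config(sampling_rate = 250, duration = 60, n_sensors = 16,
                    alpha_peak = 9, seed = 13)
  ses <- simulate_session(cfg, head = hm)
  scalp <- to_average_reference(ses$scalp)
  ab_scalp <- find_alpha_peak(welch_psd(scalp))
  expect_true(ab_scalp$peak_found)
  expect_lte(abs(ab_scalp$f_peak - 9), 0.5)

  bip <- to_bipolar(ses$intracranial, attr(ses$intracranial, "lead_layout"))
  ab_ic <- find_alpha_peak(welch_psd(bip), channels = "R1-R2")
  expect_true(ab_ic$peak_found)
  expect_lte(abs(ab_ic$f_peak - 9), 0.5)
})
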