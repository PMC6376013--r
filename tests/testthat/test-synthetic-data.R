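test_that("envelope generator is deterministic and respects its timescale", {
  e1 <- gen_envelope(2, 300, 250, seed = 7)
  e2 <- gen_envelope(2, 300, 250, seed = 7)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))
  expect_gt(mean(e1), 0)
  expect_length(e1, 75000L)

  # empirical autocorrelation oracle: 1/e decay lag within [0.5, 2] x timescale
  fs <- 50
  lags <- vapply(1:50, function(s) {
    e <- gen_envelope(2, 300, fs, seed = s)
    ac <- stats::acf(e, lag.max = 5 * fs, plot = FALSE)$acf
    (which(ac < exp(-1))[1] - 1) / fs
  }, 1.0)
  expect_true(all(lags >= 1 & lags <= 4))
})

test_that("envelope generator rejects invalid parameters", {
  expect_error(gen_envelope(0, 300, 250, seed = 1), "timescale")
  expect_error(gen_envelope(2, 0, 250, seed = 1), "duration")
})

test_that("alpha source is a narrowband carrier modulated by the envelope", {
  fs <- 250
  # constant envelope -> pure tone with PSD argmax at the carrier bin
  s <- gen_alpha_source(rep(1, 10 * fs), 9, fs, seed = 1)
  psd <- welch_psd(s, window_s = 2, fs = fs)
  fmax <- psd$freqs[which.max(psd$power[, 1])]
  expect_lt(abs(fmax - 9), 0.5 + 1e-9)

  expect_identical(gen_alpha_source(numeric(100), 9, fs, seed = 1),
                   numeric(100))
  expect_error(gen_alpha_source(rep(1, 100), 130, fs, seed = 1), "Nyquist")

  # Bedrosian condition: Hilbert envelope of the output recovers the input
  env <- gen_envelope(2, 300, fs, seed = 11)
  x <- gen_alpha_source(env, 9, fs, seed = 2)
  hil <- Mod(deepesi:::analytic_rows(x)[1, ])
  interior <- (2 * fs):(length(x) - 2 * fs)
  expect_gte(stats::cor(hil[interior], env[interior]), 0.99)
})

test_that("correlated envelope pairs realize the requested correlation", {
  p1 <- gen_correlated_envelopes(2, 1, 60, 100, seed = 3)
  expect_identical(p1[[1]], p1[[2]])
  expect_error(gen_correlated_envelopes(2, 1.2, 60, 100, seed = 3), "rho")

  # effective-sample-size bound: with a 2-s timescale over 300 s the
  # correlation estimate has SD ~ sqrt(timescale/duration) ~ 0.08, so near
  # all seeds stay below 0.15 and the ensemble mean is near 0
  fs <- 50
  r0 <- vapply(1:50, function(s) {
    p <- gen_correlated_envelopes(2, 0, 300, fs, seed = s)
    stats::cor(p[[1]], p[[2]])
  }, 1.0)
  expect_gte(mean(abs(r0) < 0.15), 0.9)
  expect_lt(abs(mean(r0)), 0.05)

  r6 <- vapply(1:50, function(s) {
    p <- gen_correlated_envelopes(2, 0.6, 300, fs, seed = 100 + s)
    stats::cor(p[[1]], p[[2]])
  }, 1.0)
  expect_true(mean(r6) > 0.5 && mean(r6) < 0.7)
  expect_gt(mean(r6 >= 0.45 & r6 <= 0.75), 0.9)
})

test_that("simulated scalp data are the lead-field projection of the sources", {
  hm <- head_model(n_sensors = 16)
  cfg <- sim_config(sampling_rate = 250, duration = 10, n_sensors = 16,
                    sensor_noise_sd = 0, lfp_noise_sd = 0, seed = 5)
  ses <- simulate_session(cfg, head = hm)
  # noiseless data lie exactly in the column space of the session gains
  gains <- ses$truth$scalp_gains
  resid <- ses$scalp$data - gains %*% qr.solve(gains, ses$scalp$data)
  expect_lt(max(abs(resid)), 1e-9 * max(abs(ses$scalp$data)))

  # doubling all source moments doubles the noiseless scalp potentials
  cfg2 <- sim_config(sampling_rate = 250, duration = 10, n_sensors = 16,
                     sensor_noise_sd = 0, lfp_noise_sd = 0, seed = 5,
                     deep_moment = 2 * cfg$deep_moment,
                     cortical_moment = 2 * cfg$cortical_moment)
  ses2 <- simulate_session(cfg2, head = hm)
  expect_equal(ses2$scalp$data, 2 * ses$scalp$data, tolerance = 1e-12)
})

test_that("sessions are deterministic and validate geometry", {
  hm <- head_model(n_sensors = 16)
  cfg <- sim_config(sampling_rate = 250, duration = 5, n_sensors = 16,
                    seed = 9)
  s1 <- simulate_session(cfg, head = hm)
  s2 <- simulate_session(cfg, head = hm)
  expect_identical(s1$scalp$data, s2$scalp$data)
  expect_identical(s1$intracranial$data, s2$intracranial$data)

  bad <- sim_config(sampling_rate = 250, duration = 5, n_sensors = 16,
                    deep_source_positions = rbind(c(-90, 0, 0), c(28, -8, 2)))
  expect_error(simulate_session(bad, head = hm), "geometry")

  # contacts are collinear along the lead trajectory
  cp <- s1$truth$contact_positions$L
  v1 <- cp[2, ] - cp[1, ]
  for (j in 2:3) {
    vj <- cp[j + 1, ] - cp[j, ]
    expect_equal(vj, v1, tolerance = 1e-9)
  }
})

test_that("uncoupled deep and cortical envelopes are uncorrelated", {
  hm <- head_model(n_sensors = 16)
  cfg <- sim_config(sampling_rate = 250, duration = 300, n_sensors = 16,
                    interhemi_rho = 0, cortico_deep_rho = 0, seed = 21)
  ses <- simulate_session(cfg, head = hm)
  env <- ses$truth$source_envelopes
  expect_lt(abs(stats::cor(env[1, ], env[2, ])), 0.2)
  for (j in 3:nrow(env)) {
    expect_lt(abs(stats::cor(env[1, ], env[j, ])), 0.2)
  }

  # and the configured interhemispheric coupling is realized
  cfg2 <- sim_config(sampling_rate = 250, duration = 300, n_sensors = 16,
                     interhemi_rho = 0.5, seed = 22)
  ses2 <- simulate_session(cfg2, head = hm)
  env2 <- ses2$truth$source_envelopes
  expect_lt(abs(stats::cor(env2[1, ], env2[2, ]) - 0.5), 0.15)
})

test_that("intracranial bipolar channels carry the deep source's alpha peak", {
  hm <- head_model(n_sensors = 16)
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(sampling_rate = 250, duration = 60, n_sensors = 16,
                      seed = s)
    ses <- simulate_session(cfg, head = hm)
    bip <- to_bipolar(ses$intracranial, attr(ses$intracranial, "lead_layout"))
    ab <- find_alpha_peak(welch_psd(bip), channels = "L1-L2")
    isTRUE(ab$peak_found) && abs(ab$f_peak - 9) <= 0.5
  }, TRUE)
  expect_true(all(hits))
})
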