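# Small hand-built inverse operator: 6 "sensors", 2 points. The operator maps
# sensor differences onto single current components so the norm-combination
# step can be checked exactly.
fake_op <- function() {
  G <- matrix(0, 6, 6)
  G[1, 1] <- 0.5; G[1, 2] <- -0.5   # point 1, x component <- ch1 - ch2
  G[2, 3] <- 0.5; G[2, 4] <- -0.5   # point 1, y component <- ch3 - ch4
  src <- structure(list(points = rbind(c(0, 0, 10), c(0, 0, -10)),
                        spacing = 20,
                        grid_index = rbind(c(0, 0, 0), c(0, 0, -1))),
                   class = "source_space")
  structure(list(G = G, lambda = 0, neighbor_radius = 0, weight_exponent = 2,
                 n_sensors = 6, n_points = 2, src = src),
            class = "inverse_operator")
}

narrowband_rec <- function(data, fs = 250) {
  rec <- recording(data, fs, reference = "average")
  attr(rec, "band") <- c(8, 10)
  attr(rec, "edge_excl_s") <- 1
  rec
}

test_that("combined xyz norm equals the single active component's magnitude", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  s <- gen_envelope(2, 20, fs, seed = 2) * cos(2 * pi * 9 * t)
  X <- matrix(0, 6, length(s))
  X[1, ] <- s; X[2, ] <- -s # zero-mean columns, activates only point-1 x
  fld <- source_envelopes(fake_op(), narrowband_rec(X), decimate_to = NULL)
  hil <- Mod(deepesi:::analytic_rows(s)[1, ])
  expect_lt(max(abs(fld$env[1, ] - hil)), 1e-8)
  expect_true(all(fld$env[2, ] == 0))

  # two equal components combine as sqrt(2) times one
  X2 <- X
  X2[3, ] <- s; X2[4, ] <- -s
  fld2 <- source_envelopes(fake_op(), narrowband_rec(X2), decimate_to = NULL)
  expect_equal(fld2$env[1, ], sqrt(2) * fld$env[1, ], tolerance = 1e-10)
})

test_that("envelope fields are phase-invariant and scale-equivariant", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  # strictly band-limited modulation with integer cycle counts: the 90-degree
  # carrier shift must leave the envelope field numerically unchanged
  A <- 2 + 0.5 * cos(2 * pi * 0.3 * t) + 0.3 * sin(2 * pi * 0.5 * t)
  mk <- function(carrier) {
    X <- matrix(0, 6, length(t))
    X[1, ] <- A * carrier; X[2, ] <- -X[1, ]
    narrowband_rec(X)
  }
  f_cos <- source_envelopes(fake_op(), mk(cos(2 * pi * 9 * t)),
                            decimate_to = NULL)
  f_sin <- source_envelopes(fake_op(), mk(sin(2 * pi * 9 * t)),
                            decimate_to = NULL)
  interior <- f_cos$keep
  rel <- abs(f_cos$env[1, interior] - f_sin$env[1, interior]) /
    max(f_cos$env[1, interior])
  expect_lt(max(rel), 1e-6)

  rec <- mk(cos(2 * pi * 9 * t))
  rec3 <- rec; rec3$data <- -3 * rec3$data
  f3 <- source_envelopes(fake_op(), rec3, decimate_to = NULL)
  expect_equal(f3$env, 3 * f_cos$env, tolerance = 1e-12)

  # zero data -> zero field
  fz <- source_envelopes(fake_op(), narrowband_rec(matrix(0, 6, 1000)))
  expect_true(all(fz$env == 0))
})

test_that("decimation is exact subsampling of the full-rate envelope field", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  s <- gen_envelope(2, 20, fs, seed = 3) * cos(2 * pi * 9 * t)
  X <- matrix(0, 6, length(s)); X[1, ] <- s; X[2, ] <- -s
  full <- source_envelopes(fake_op(), narrowband_rec(X), decimate_to = NULL)
  dec <- source_envelopes(fake_op(), narrowband_rec(X), decimate_to = 25)
  idx <- seq(1, ncol(full$env), by = 10)
  expect_identical(dec$env, full$env[, idx])
  expect_equal(dec$fs, 25)
})

test_that("Hilbert-then-invert commutes with invert-then-Hilbert", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  s <- gen_envelope(2, 10, fs, seed = 9) * cos(2 * pi * 9 * t)
  X <- matrix(0, 6, length(s)); X[1, ] <- s; X[2, ] <- -s
  fld <- source_envelopes(fake_op(), narrowband_rec(X), decimate_to = NULL)
  cur <- fake_op()$G %*% X # invert first...
  env_alt <- Mod(deepesi:::analytic_rows(cur[1, , drop = FALSE]))[1, ]
  expect_lt(max(abs(fld$env[1, ] - env_alt)), 1e-8)
})

test_that("spatial threshold zeroes strictly-below-mean entries per frame", {
  mk_field <- function(env) {
    structure(list(env = env, fs = 25, times = (seq_len(ncol(env)) - 1) / 25,
                   keep = rep(TRUE, ncol(env)), band = c(8, 10),
                   thresholded = FALSE, src = NULL, seg_bounds = integer(0)),
              class = "envelope_field")
  }
  f <- spatial_threshold(mk_field(matrix(c(1, 2, 3, 4), 4, 1)))
  expect_equal(as.numeric(f$env), c(0, 0, 3, 4)) # mean 2.5

  # constant frame unchanged: ties at the mean are kept
  fc <- spatial_threshold(mk_field(matrix(7, 3, 2)))
  expect_true(all(fc$env == 7))

  set.seed(5)
  env <- matrix(stats::rexp(50 * 20), 50, 20)
  ft <- spatial_threshold(mk_field(env))
  for (j in seq_len(20)) {
    expect_equal(sum(ft$env[, j] == 0), sum(env[, j] < mean(env[, j])))
  }

  expect_error(spatial_threshold(ft), "already")
  expect_true(ft$thresholded)
})

test_that("a noiseless deep source's envelope is recovered at the nearest point", {
  ts <- toy_setup()
  fs <- 250
  dur <- 60
  pos <- c(-28, -8, 2)
  env_true <- gen_envelope(2, dur, fs, seed = 14)
  s <- env_true * cos(2 * pi * 9 * (0:(dur * fs - 1)) / fs)
  g <- dipole_potential(ts$head, pos, 25 * c(0.2, 0.5, 0.84))
  g <- g - mean(g)
  rec <- recording(outer(g, s), fs, reference = "average")
  nb <- bandpass(rec, c(8, 10))
  op <- build_laura_operator(ts$L, ts$src, lambda = 1e-4)
  fld <- source_envelopes(op, nb)
  nearest <- which.min(rowSums(sweep(ts$src$points, 2, pos)^2))
  idx <- round(fld$times[fld$keep] * fs) + 1
  expect_gte(stats::cor(fld$env[nearest, fld$keep], env_true[idx]), 0.95)
})

test_that("source_envelopes validates its input provenance", {
  op <- fake_op()
  rec <- recording(matrix(0, 6, 100), 250, reference = "average")
  expect_error(source_envelopes(op, rec), "band")
  rec2 <- recording(matrix(1, 6, 100), 250, reference = "vertex")
  attr(rec2, "band") <- c(8, 10)
  expect_error(source_envelopes(op, rec2), "average-referenced")
})
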