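mk_field <- function(env, src = NULL, fs = 25) {
  structure(list(env = env, fs = fs, times = (seq_len(ncol(env)) - 1) / fs,
                 keep = rep(TRUE, ncol(env)), band = c(8, 10),
                 thresholded = TRUE, src = src, seg_bounds = integer(0)),
            class = "envelope_field")
}

line_src <- function(n, spacing = 4) {
  structure(list(points = cbind(seq_len(n) * spacing, 0, 0),
                 spacing = spacing,
                 grid_index = cbind(seq_len(n), 0, 0)),
            class = "source_space")
}

test_that("correlation maps match a direct per-point oracle, negatives zeroed", {
  set.seed(7)
  src <- line_src(30)
  env <- matrix(rnorm(30 * 400), 30)
  ref <- env[4, ] # exact match at point 4
  fld <- mk_field(env, src)
  map <- envelope_correlation_map(fld, ref)
  expect_equal(map$r[4], 1)
  expect_equal(map$r_raw, naive_cor_map(env, ref), tolerance = 1e-12)
  expect_true(all(map$r >= 0))

  # anticorrelated point stored as zero
  env2 <- env; env2[9, ] <- -0.8 * ref + 0.2 * rnorm(400)
  map2 <- envelope_correlation_map(mk_field(env2, src), ref)
  expect_lt(stats::cor(env2[9, ], ref), -0.5)
  expect_identical(map2$r[9], 0)

  # constant rows are reported and zeroed
  env3 <- env; env3[2, ] <- 5
  expect_message(map3 <- envelope_correlation_map(mk_field(env3, src), ref),
                 "undefined")
  expect_identical(map3$r[2], 0)

  # invariance to positive affine rescaling of either input
  map4 <- envelope_correlation_map(mk_field(3 * env + 7, src), 2 * ref - 1)
  expect_equal(map4$r, map$r, tolerance = 1e-12)
})

test_that("independent slow envelopes rarely exceed |r| = 0.2 at 300 s", {
  fs <- 25
  frac_high <- vapply(1:20, function(s) {
    a <- gen_envelope(2, 300, fs, seed = s)
    b <- t(vapply(1:30, function(j) gen_envelope(2, 300, fs,
                                                 seed = 10000 + 30 * s + j),
                  numeric(300 * fs)))
    fld <- mk_field(b, line_src(30), fs = fs)
    map <- envelope_correlation_map(fld, a)
    mean(abs(map$r_raw) >= 0.2)
  }, 1.0)
  expect_lt(mean(frac_high), 0.05)
})

test_that("cross-correlation lag curves identify shifts at sample resolution", {
  set.seed(11)
  fs <- 25
  a <- gen_envelope(2, 120, fs, seed = 31)
  lc <- cross_correlation_lags(a, a, max_lag_s = 5, fs = fs)
  expect_equal(lc$r[lc$lag == 0], 1)
  expect_equal(lc$lag[which.max(lc$r)], 0L)

  shift <- round(1.2 * fs)
  b <- c(rep(mean(a), shift), a[1:(length(a) - shift)]) # a delayed by 1.2 s
  lc2 <- cross_correlation_lags(a, b, max_lag_s = 5, fs = fs)
  expect_equal(lc2$lag_s[which.max(lc2$r)], 1.2)

  expect_error(cross_correlation_lags(rep(1, 100), a[1:100], 1, fs),
               "constant")
  expect_error(cross_correlation_lags(a, a, 40, fs), "quarter")
})

test_that("distance profiles bin correlations around the contact", {
  src <- line_src(25, spacing = 4) # points at 4, 8, ..., 100 mm
  contact <- c(0, 0, 0)
  # uniform map -> all occupied bins share the same mean
  unif <- mk_field(matrix(1, 25, 10), src)
  map_u <- suppressMessages(
    envelope_correlation_map(unif, stats::rnorm(10)))
  map_u$r <- rep(0.4, 25)
  prof <- distance_profile(map_u, src, contact, bin_mm = 4)
  occ <- prof[prof$n > 0, ]
  expect_true(all(occ$mean_r == 0.4))
  # 4-mm bins: one point per bin along the line
  expect_true(all(occ$n == 1))
  expect_equal(occ$bin_lo[1], 4)

  # peaked map decays with distance beyond the peak bin
  map_p <- map_u
  map_p$r <- exp(-(seq_len(25) * 4) / 30)
  prof_p <- distance_profile(map_p, src, contact, bin_mm = 4)
  means <- prof_p$mean_r[prof_p$n > 0]
  expect_true(all(diff(means) < 0))

  expect_error(distance_profile(map_u, src, contact, bin_mm = 0), "bin_mm")
})

test_that("localization reports pick the nearest significant cluster", {
  src <- line_src(25, spacing = 4)
  env <- matrix(stats::rexp(25 * 50), 25)
  fld <- mk_field(env, src)
  map <- suppressMessages(envelope_correlation_map(fld, stats::rnorm(50)))

  sig_from <- function(flags, thr = 0.5) {
    out <- tibble::tibble(point = seq_len(25), r = map$r, significant = flags)
    class(out) <- c("significance_map", class(out))
    attr(out, "alpha") <- 0.01
    attr(out, "threshold_r") <- thr
    out
  }

  # single significant point 20 mm from the contact
  flags <- rep(FALSE, 25); flags[5] <- TRUE # point at x = 20
  map$r <- rep(0, 25); map$r[5] <- 0.9
  rep1 <- localization_report(map, sig_from(flags), src, c(0, 0, 0))
  expect_true(rep1$significant)
  expect_equal(rep1$distance_mm, 20)
  expect_equal(rep1$range_min_mm, 20)
  expect_equal(rep1$range_max_mm, 20)

  # cluster max at the contact itself -> distance 0
  flags2 <- rep(FALSE, 25); flags2[1:3] <- TRUE
  map$r <- rep(0, 25); map$r[1:3] <- c(0.9, 0.6, 0.5)
  rep2 <- localization_report(map, sig_from(flags2), src, c(4, 0, 0))
  expect_equal(rep2$distance_mm, 0)
  expect_equal(rep2$cluster_size, 3L)
  expect_equal(rep2$range_max_mm, 8) # farthest cluster member at x = 12

  # two clusters: the one closest to the contact is reported
  flags3 <- rep(FALSE, 25); flags3[c(2, 3, 20, 21)] <- TRUE
  map$r <- rep(0, 25); map$r[c(2, 3, 20, 21)] <- c(0.5, 0.6, 0.95, 0.9)
  rep3 <- localization_report(map, sig_from(flags3), src, c(6, 0, 0))
  expect_equal(rep3$peak_x, 12) # r-max of the NEAR cluster, not the global max

  # no significant point -> not-significant report
  rep4 <- localization_report(map, sig_from(rep(FALSE, 25)), src, c(0, 0, 0))
  expect_false(rep4$significant)
  expect_true(is.na(rep4$distance_mm))

  # translation invariance of the reported distance
  src2 <- line_src(25, spacing = 4)
  src2$points <- sweep(src2$points, 2, c(-10, 5, 30), `+`)
  rep5 <- localization_report(map, sig_from(flags3), src2,
                              c(6, 0, 0) + c(-10, 5, 30))
  expect_equal(rep5$distance_mm, rep3$distance_mm)
})

test_that("window robustness degenerates correctly for the full-record window", {
  set.seed(13)
  src <- line_src(20)
  env <- matrix(stats::rexp(20 * 500), 20)
  fld <- mk_field(env, src)
  ref <- env[7, ] + 0.3 * stats::rnorm(500)
  wr <- window_robustness(fld, ref, window_sizes = 500 / 25)
  expect_equal(wr$n_windows, 1L)
  expect_equal(wr$sd_r, 0)
  expect_equal(wr$mean_map_similarity, 1)

  # white-noise reference: near-zero mean correlation at every size
  wn <- suppressMessages(
    window_robustness(fld, stats::rnorm(500), window_sizes = c(5, 10)))
  expect_true(all(abs(wn$mean_r) < 0.25))

  expect_error(window_robustness(fld, ref, window_sizes = 100), "longer")
})
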