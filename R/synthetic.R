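#' Simulation configuration
#'
#' Fully specifies a synthetic recording session: bilateral deep alpha sources
#' with slow envelope dynamics and tunable interhemispheric envelope
#' correlation, additional cortical alpha sources loosely coupled to the deep
#' ones, volume conduction through the spherical head model to the scalp
#' montage, sensor noise, and intracranial lead recordings dominated by the
#' local deep source.
#'
#' Default amplitudes emulate eyes-closed rest: posterior-dominant cortical
#' alpha of order 10 uV at the scalp and a deep contribution well below it.
#' `deep_moment` is the free knob controlling the deep sources'
#' signal-to-noise ratio at the scalp.
#'
#' @param sampling_rate Hz (default 1000; reducible for desk-scale runs).
#' @param duration seconds of recording (default 300, i.e. 5 min rest).
#' @param n_sensors scalp electrode count (default 256).
#' @param alpha_peak deep-source alpha frequency in Hz, one value or one per
#'   deep source (default 9, within the 8-10 Hz range of interest).
#' @param envelope_timescale autocorrelation time of the amplitude envelopes
#'   in seconds (default 2; the dynamics of interest live on the scale of
#'   seconds).
#' @param interhemi_rho target Pearson correlation of the left/right deep
#'   envelopes, in `[0, 1]` (default 0.5).
#' @param n_cortical_sources count of cortical alpha sources (default 4).
#' @param cortico_deep_rho target envelope correlation between each cortical
#'   source and the deep source of its hemisphere, in `[0, 1]` (default 0.3).
#' @param sensor_noise_sd scalp sensor noise SD in uV (default 1).
#' @param lfp_noise_sd intracranial contact noise SD in uV (default 2).
#' @param deep_source_positions 2 x 3 matrix (mm) of deep source locations;
#'   the default sits at thalamic-like eccentricity (~0.36 of the brain
#'   radius) in each hemisphere.
#' @param deep_moment dipole moment scale of each deep source, nAm
#'   (default 25).
#' @param cortical_moment dipole moment scale of each cortical source, nAm
#'   (default 60).
#' @param lfp_gain local field coupling of the deep source at zero distance,
#'   uV per nAm of source current (default 1.2); the recorded local field
#'   scales with the same source strength as the scalp projection, so a
#'   silenced source (zero moment) leaves no intracranial alpha either.
#' @param contact_spacing_mm centre-to-centre spacing of the 4 lead contacts
#'   (default 2; DBS leads come with 1.5 mm or 0.5 mm inter-contact gaps).
#' @param envelope_shift positivity shift of the rectified envelope process,
#'   in SD units of the latent Gaussian (default 2).
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 1000, duration = 300, n_sensors = 256,
                       alpha_peak = 9, envelope_timescale = 2,
                       interhemi_rho = 0.5, n_cortical_sources = 4,
                       cortico_deep_rho = 0.3, sensor_noise_sd = 1,
                       lfp_noise_sd = 2,
                       deep_source_positions = rbind(c(-28, -8, 2),
                                                     c(28, -8, 2)),
                       deep_moment = 25, cortical_moment = 60, lfp_gain = 1.2,
                       contact_spacing_mm = 2, envelope_shift = 2, seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              n_sensors = n_sensors, alpha_peak = alpha_peak,
              envelope_timescale = envelope_timescale,
              interhemi_rho = interhemi_rho,
              n_cortical_sources = n_cortical_sources,
              cortico_deep_rho = cortico_deep_rho,
              sensor_noise_sd = sensor_noise_sd,
              lfp_noise_sd = lfp_noise_sd,
              deep_source_positions = as.matrix(deep_source_positions),
              deep_moment = deep_moment, cortical_moment = cortical_moment,
              lfp_gain = lfp_gain, contact_spacing_mm = contact_spacing_mm,
              envelope_shift = envelope_shift, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_scalar_num(cfg$sampling_rate, "sampling_rate",
                    lower = .Machine$double.eps)
  assert_scalar_num(cfg$duration, "duration", lower = .Machine$double.eps)
  if (any(cfg$alpha_peak <= 0) ||
      cfg$sampling_rate <= 2 * (max(cfg$alpha_peak) + 1)) {
    stop("sampling_rate must exceed 2*(alpha_peak + 1)", call. = FALSE)
  }
  assert_scalar_num(cfg$envelope_timescale, "envelope_timescale",
                    lower = .Machine$double.eps)
  assert_scalar_num(cfg$interhemi_rho, "interhemi_rho", 0, 1)
  assert_scalar_num(cfg$cortico_deep_rho, "cortico_deep_rho", 0, 1)
  assert_scalar_num(cfg$sensor_noise_sd, "sensor_noise_sd", 0)
  assert_scalar_num(cfg$lfp_noise_sd, "lfp_noise_sd", 0)
  if (ncol(cfg$deep_source_positions) != 3L ||
      nrow(cfg$deep_source_positions) != 2L) {
    stop("`deep_source_positions` must be a 2 x 3 matrix", call. = FALSE)
  }
  n_samp <- cfg$duration * cfg$sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("duration * sampling_rate must be an integer sample count",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Slow positive amplitude envelope
#'
#' Ornstein-Uhlenbeck-style smoothed Gaussian noise, shifted by `shift`
#' standard deviations and rectified to nonnegativity. The latent process has
#' an exponential autocorrelation with time constant `timescale`, so the
#' envelope's autocorrelation decays on the order of `timescale` (seconds).
#'
#' @param timescale autocorrelation time constant in seconds (> 0).
#' @param duration series duration in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed; the output is deterministic given the seed.
#' @param shift positivity shift in latent SD units (default 2).
#' @return Nonnegative numeric vector of length `duration * fs` with strictly
#'   positive mean.
#' @export
gen_envelope <- function(timescale, duration, fs, seed, shift = 2) {
  assert_scalar_num(timescale, "timescale", lower = .Machine$double.eps)
  assert_scalar_num(duration, "duration", lower = .Machine$double.eps)
  n <- round(duration * fs)
  z <- with_seed(seed, stats::rnorm(n + 1L))
  ou_rectify(z, timescale, fs, shift)
}

# Latent standard-normal innovations -> stationary unit-variance OU sample
# path -> shifted/rectified envelope. The first innovation seeds the
# stationary initial state.
ou_rectify <- function(innov, timescale, fs, shift) {
  a <- exp(-1 / (fs * timescale))
  x <- stats::filter(innov[-1L] * sqrt(1 - a^2), a, method = "recursive",
                     init = innov[1L])
  pmax(as.numeric(x) + shift, 0)
}

#' Amplitude-modulated alpha oscillation
#'
#' Multiplies a slow nonnegative envelope onto a sinusoidal carrier near the
#' individual alpha frequency. Because the envelope is band-limited far below
#' the carrier (Bedrosian's condition), the Hilbert envelope of the output
#' recovers the input envelope.
#'
#' @param envelope nonnegative amplitude series.
#' @param f_peak carrier frequency in Hz, inside `(0, fs/2)`.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed for the carrier's random initial phase.
#' @return Numeric series of `length(envelope)` samples.
#' @export
gen_alpha_source <- function(envelope, f_peak, fs, seed) {
  if (f_peak <= 0 || f_peak >= fs / 2) {
    stop("`f_peak` must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  t <- (seq_along(envelope) - 1L) / fs
  envelope * cos(2 * pi * f_peak * t + phase)
}

# Expected Pearson correlation of the pair (f(X), f(Y)), f(x) = max(x+s, 0),
# for standard bivariate normal (X, Y) with correlation w, by tensorized
# Gauss-Hermite quadrature. Used to calibrate the latent mixing weight.
rectified_corr <- function(w, shift, n_nodes = 40L) {
  gh <- pracma::gaussHermite(n_nodes)
  x <- sqrt(2) * gh$x
  wt <- gh$w / sqrt(pi)
  f <- function(v) pmax(v + shift, 0)
  m1 <- sum(wt * f(x))
  m2 <- sum(wt * f(x)^2)
  v <- m2 - m1^2
  # E[f(X) f(Y)] with Y = w X + sqrt(1-w^2) Z over the (X, Z) grid
  XY <- outer(x, x, function(u, z) f(u) * f(w * u + sqrt(1 - w^2) * z))
  e_xy <- as.numeric(t(wt) %*% XY %*% wt)
  (e_xy - m1^2) / v
}

#' Pair of envelopes with calibrated correlation
#'
#' Two envelope processes built by mixing a shared and a private latent
#' Gaussian process before rectification. Rectification attenuates the latent
#' correlation, so the mixing weight is calibrated numerically (Gauss-Hermite
#' quadrature plus root finding) such that the realized Pearson correlation of
#' the rectified envelopes converges to `rho`.
#'
#' @inheritParams gen_envelope
#' @param rho target Pearson correlation in `[0, 1]`.
#' @return List of two nonnegative envelope series.
#' @export
gen_correlated_envelopes <- function(timescale, rho, duration, fs, seed,
                                     shift = 2) {
  assert_scalar_num(rho, "rho", 0, 1)
  n <- round(duration * fs)
  z <- with_seed(seed, matrix(stats::rnorm(3L * (n + 1L)), ncol = 3L))
  w <- calibrate_mixing(rho, shift)
  lat1 <- sqrt(w) * z[, 1] + sqrt(1 - w) * z[, 2]
  lat2 <- sqrt(w) * z[, 1] + sqrt(1 - w) * z[, 3]
  list(ou_rectify(lat1, timescale, fs, shift),
       ou_rectify(lat2, timescale, fs, shift))
}

# Invert rectified_corr: latent correlation w achieving envelope correlation
# rho after shift/rectification.
calibrate_mixing <- function(rho, shift) {
  if (rho <= 0) return(0)
  if (rho >= 1) return(1)
  stats::uniroot(function(w) rectified_corr(w, shift) - rho,
                 interval = c(0, 1), tol = 1e-6)$root
}

#' Simulate a full synthetic session
#'
#' Generates one synchronized session on a common time base: average-referenced
#' scalp EEG (lead-field projection of all sources plus white sensor noise),
#' intracranial 4-contact lead recordings per hemisphere (local deep source
#' with amplitude falling off as `1/(1 + d)` with distance, a common far-field
#' term removed by bipolar derivation, plus contact noise), and the ground
#' truth (source positions, envelopes, contact positions).
#'
#' @param cfg a [sim_config()].
#' @param head a [head_model()]; by default one is built with the config's
#'   sensor count. The source space used for later imaging may be passed as
#'   `src` for interface symmetry but is not needed by the simulator.
#' @param src optional [build_source_space()] (unused; accepted for pipeline
#'   symmetry).
#' @return A `sim_session` list: `scalp` and `intracranial` [recording()]s,
#'   `truth` (ground truth), `cfg`, `head`.
#' @export
simulate_session <- function(cfg, head = NULL, src = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  if (is.null(head)) head <- head_model(n_sensors = cfg$n_sensors)
  if (nrow(head$sensors) != cfg$n_sensors) {
    stop("head model sensor count disagrees with the config", call. = FALSE)
  }
  r1 <- head$shell_radii[1]
  deep_pos <- cfg$deep_source_positions
  if (any(sqrt(rowSums(deep_pos^2)) >= r1)) {
    stop("geometry error: deep source outside the brain shell", call. = FALSE)
  }
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  f_deep <- rep(cfg$alpha_peak, length.out = 2L)
  nc <- cfg$n_cortical_sources

  out <- with_seed(cfg$seed, {
    # --- envelopes -------------------------------------------------------
    w_deep <- calibrate_mixing(cfg$interhemi_rho, cfg$envelope_shift)
    w_cort <- calibrate_mixing(cfg$cortico_deep_rho, cfg$envelope_shift)
    z_shared <- stats::rnorm(n + 1L)
    z_L <- stats::rnorm(n + 1L)
    z_R <- stats::rnorm(n + 1L)
    lat_deep <- list(
      L = sqrt(w_deep) * z_shared + sqrt(1 - w_deep) * z_L,
      R = sqrt(w_deep) * z_shared + sqrt(1 - w_deep) * z_R
    )
    env_deep <- lapply(lat_deep, ou_rectify, timescale =
                         cfg$envelope_timescale, fs = fs,
                       shift = cfg$envelope_shift)
    env_cort <- list()
    lat_cort <- list()
    if (nc > 0) {
      for (j in seq_len(nc)) {
        side <- if (j %% 2L == 1L) "L" else "R"
        zp <- stats::rnorm(n + 1L)
        lat <- sqrt(w_cort) * lat_deep[[side]] + sqrt(1 - w_cort) * zp
        lat_cort[[j]] <- lat
        env_cort[[j]] <- ou_rectify(lat, cfg$envelope_timescale, fs,
                                    cfg$envelope_shift)
      }
    }
    # --- source geometry and carriers -----------------------------------
    cort_pos <- matrix(0, 0, 3L)
    f_cort <- numeric(0)
    if (nc > 0) {
      rad <- 0.85 * r1
      theta <- stats::runif(nc, 0, pi * 0.55)   # upper sphere, down to ~100 deg
      phi <- stats::runif(nc, 0, 2 * pi)
      cort_pos <- rad * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                              cos(theta))
      # alternate hemispheres to match the envelope coupling sides
      cort_pos[, 1] <- abs(cort_pos[, 1]) *
        ifelse(seq_len(nc) %% 2L == 1L, -1, 1)
      f_cort <- stats::runif(nc, mean(f_deep) - 0.5, mean(f_deep) + 0.5)
    }
    all_pos <- rbind(deep_pos, cort_pos)
    n_src <- nrow(all_pos)
    orient <- matrix(stats::rnorm(3L * n_src), ncol = 3L)
    orient <- orient / sqrt(rowSums(orient^2))
    phases <- stats::runif(n_src, 0, 2 * pi)
    t <- (seq_len(n) - 1L) / fs
    freqs <- c(f_deep, f_cort)
    moments <- c(rep(cfg$deep_moment, 2L), rep(cfg$cortical_moment, nc))
    envs <- c(env_deep, env_cort)
    signals <- matrix(0, n_src, n)
    for (i in seq_len(n_src)) {
      signals[i, ] <- envs[[i]] * cos(2 * pi * freqs[i] * t + phases[i])
    }
    # --- scalp projection ------------------------------------------------
    gains <- vapply(seq_len(n_src), function(i) {
      g <- dipole_potential(head, all_pos[i, ], moments[i] * orient[i, ])
      g - mean(g)
    }, numeric(cfg$n_sensors))
    scalp_data <- gains %*% signals
    if (cfg$sensor_noise_sd > 0) {
      scalp_data <- scalp_data +
        matrix(stats::rnorm(length(scalp_data), sd = cfg$sensor_noise_sd),
               nrow(scalp_data))
    }
    # --- intracranial leads ----------------------------------------------
    traj <- c(0.25, 0.35, 0.9)
    traj <- traj / sqrt(sum(traj^2))
    contacts <- list()
    lfp <- list()
    for (s in 1:2) {
      dirn <- traj * c(sign(deep_pos[s, 1]), 1, 1)
      cpos <- t(vapply(0:3, function(j) {
        deep_pos[s, ] + (0.5 + j * cfg$contact_spacing_mm) * dirn
      }, numeric(3)))
      contacts[[s]] <- cpos
      mids <- (cpos[-4, ] + cpos[-1, ]) / 2
      d_mid <- sqrt(rowSums(sweep(mids, 2L, deep_pos[s, ])^2))
      bip_scale <- cfg$lfp_gain * cfg$deep_moment / (1 + d_mid)
      # contact potentials whose adjacent differences realize the bipolar
      # model exactly (deeper minus shallower)
      u <- c(rev(cumsum(rev(bip_scale))), 0)
      far_field <- if (nc > 0) {
        0.05 * cfg$lfp_gain * cfg$cortical_moment *
          colSums(signals[-(1:2), , drop = FALSE])
      } else {
        numeric(n)
      }
      sig <- outer(u, signals[s, ]) +
        matrix(far_field, 4L, n, byrow = TRUE)
      if (cfg$lfp_noise_sd > 0) {
        sig <- sig + matrix(stats::rnorm(4L * n, sd = cfg$lfp_noise_sd), 4L)
      }
      lfp[[s]] <- sig
    }
    list(scalp_data = scalp_data, gains = gains, signals = signals,
         envs = envs, all_pos = all_pos, orient = orient, freqs = freqs,
         contacts = contacts, lfp = lfp)
  })

  scalp <- recording(out$scalp_data, fs,
                     labels = sprintf("E%03d", seq_len(cfg$n_sensors)),
                     positions = head$sensors, reference = "raw")
  ic_labels <- c(paste0("L", 1:4), paste0("R", 1:4))
  intracranial <- recording(rbind(out$lfp[[1]], out$lfp[[2]]), fs,
                            labels = ic_labels,
                            positions = rbind(out$contacts[[1]],
                                              out$contacts[[2]]),
                            reference = "mastoid")
  attr(intracranial, "lead_layout") <- list(L = paste0("L", 1:4),
                                            R = paste0("R", 1:4))
  truth <- list(
    source_positions = out$all_pos,
    source_envelopes = do.call(rbind, out$envs),
    source_freqs = out$freqs,
    source_orientations = out$orient,
    contact_positions = stats::setNames(out$contacts, c("L", "R")),
    deep_idx = 1:2,
    scalp_gains = out$gains
  )
  structure(list(scalp = scalp, intracranial = intracranial, truth = truth,
                 cfg = cfg, head = head),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %g s @ %g Hz, %d scalp + %d intracranial channels, %d sources\n",
              x$cfg$duration, x$cfg$sampling_rate, nrow(x$scalp$data),
              nrow(x$intracranial$data), nrow(x$truth$source_positions)))
  invisible(x)
}
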