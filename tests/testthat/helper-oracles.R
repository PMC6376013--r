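# Independent oracles and small fixtures shared across tests.

# Closed-form surface potential of a dipole inside a HOMOGENEOUS conducting
# sphere with insulating boundary, via generating-function identities for the
# Legendre sums (no series truncation). Positions in mm, moment in nAm,
# output in uV, matching the package's unit convention.
homog_sphere_potential <- function(pos, moment, sensors, R, sigma) {
  b <- sqrt(sum(pos^2))
  stopifnot(b > 0, b < R)
  x <- b / R
  r0 <- pos / b
  S <- sensors / R
  cg <- pmin(1, pmax(-1, as.numeric(S %*% r0)))
  rho <- sqrt(1 - 2 * x * cg + x^2)
  Sr <- 2 * (cg - x) / rho^3 + (1 / rho - 1) / x
  St <- 2 / rho^3 + (rho + 1) / (rho * (1 - x * cg + rho))
  m_r <- sum(moment * r0)
  m_t <- moment - m_r * r0
  K <- 1000 / (4 * pi * sigma * R^2)
  K * (m_r * Sr + St * as.numeric((S - outer(cg, r0)) %*% m_t))
}

# Small reusable head/source-space/lead-field fixture (built once per test
# run; modest sizes keep the suite fast).
toy_head <- function(n_sensors = 32) head_model(n_sensors = n_sensors)

toy_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hm <- head_model(n_sensors = 32)
      src <- build_source_space(hm, 150)
      L <- build_leadfield(hm, src)
      cache <<- list(head = hm, src = src, L = L)
    }
    cache
  }
})

# Classical regularized minimum-norm operator, the analytic reduction of the
# LAURA operator when the autoregressive term is the identity.
classical_mne <- function(gain, lambda) {
  n <- nrow(gain)
  t(gain) %*% solve(gain %*% t(gain) + lambda * diag(n))
}

# Reduced-scale simulation config used by pipeline-level tests.
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 250, duration = 60, n_sensors = 32,
                   n_cortical_sources = 2, seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Direct (loop-based) Pearson correlation map used as an oracle against the
# vectorized implementation.
naive_cor_map <- function(env, ref) {
  apply(env, 1L, function(row) {
    if (stats::sd(row) == 0 || stats::sd(ref) == 0) return(0)
    stats::cor(row, ref)
  })
}
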