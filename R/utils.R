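# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level streams.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Analytic signal of each row of a real matrix via the FFT one-sided
# spectrum doubling construction.
analytic_rows <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  out <- matrix(0i, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    z <- stats::fft(x[i, ]) * h
    out[i, ] <- stats::fft(z, inverse = TRUE) / n
  }
  out
}

# Zero-phase application of a symmetric (linear-phase) FIR kernel to each row
# of `x` by FFT convolution, compensating the group delay exactly.
fir_filter_rows <- function(x, h) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  nh <- length(h)
  stopifnot(nh %% 2L == 1L) # odd tap count -> integer group delay
  gd <- (nh - 1L) / 2L
  n <- ncol(x)
  nfft <- stats::nextn(n + nh - 1L, 2L)
  H <- stats::fft(c(h, numeric(nfft - nh)))
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(x[i, ], numeric(nfft - n)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[i, ] <- y[(gd + 1L):(gd + n)]
  }
  out
}

# Pearson correlation of each row of `m` (points x samples) against vector v,
# with zero-variance rows mapped to `fill`.
row_cor <- function(m, v, fill = 0) {
  mc <- m - rowMeans(m)
  vc <- v - mean(v)
  denom_m <- sqrt(rowSums(mc^2))
  denom_v <- sqrt(sum(vc^2))
  r <- as.numeric(mc %*% vc)
  bad <- denom_m <= .Machine$double.eps * sqrt(ncol(m)) | denom_v == 0
  r <- r / (denom_m * denom_v)
  r[bad] <- fill
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
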