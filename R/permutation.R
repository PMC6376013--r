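#' Lag-shift max-statistic permutation null
#'
#' Builds the family-wise null distribution of the map-wide maximum
#' correlation by circularly shifting the reference envelope with randomized
#' lags and recomputing the per-point correlations (negatives zeroed, as in
#' the observed map). Lags within `min_lag_s` of zero alignment are excluded
#' because alpha amplitude envelopes stay autocorrelated on that scale; when
#' the record was concatenated from segments, lags that would align a wrap
#' point within `min_lag_s` of a seam are excluded as well.
#'
#' @param field an [source_envelopes()] result (thresholded or not, matching
#'   how the observed map was computed).
#' @param ref_env reference envelope on the field's time grid.
#' @param n_perm number of permutations (default 1e4; values below 100 warn).
#' @param min_lag_s minimum admissible absolute lag in seconds (default 2).
#' @param seed RNG seed for the lag draws.
#' @param method `"random"` draws lags uniformly with replacement;
#'   `"exhaustive"` enumerates every admissible lag once (useful for exact
#'   small-sample nulls), ignoring `n_perm`.
#' @return A `permutation_null` with fields `max_stats`, `lags` (samples),
#'   `n_perm`, `min_lag_s`, `seed`.
#' @export
build_null <- function(field, ref_env, n_perm = 1e4, min_lag_s = 2,
                       seed = 1L, method = c("random", "exhaustive")) {
  stopifnot(inherits(field, "envelope_field"))
  method <- match.arg(method)
  Tn <- ncol(field$env)
  if (length(ref_env) != Tn) {
    stop("reference envelope and field must share a time base", call. = FALSE)
  }
  lags_ok <- admissible_lags(Tn, field$fs, min_lag_s, field$seg_bounds)
  if (length(lags_ok) == 0L) {
    stop("no admissible lag: record too short for the lag exclusion",
         call. = FALSE)
  }
  if (method == "random") {
    if (n_perm < 100) warning("fewer than 100 permutations", call. = FALSE)
    lags <- with_seed(seed, sample(lags_ok, n_perm, replace = TRUE))
  } else {
    lags <- lags_ok
    n_perm <- length(lags)
  }
  keep <- field$keep
  E <- field$env[, keep, drop = FALSE]
  Ec <- E - rowMeans(E)
  En <- Ec / pmax(sqrt(rowSums(Ec^2)), .Machine$double.eps)
  max_stats <- numeric(length(lags))
  block <- 250L
  t_idx <- seq_len(Tn)
  for (b0 in seq(1L, length(lags), by = block)) {
    bi <- b0:min(b0 + block - 1L, length(lags))
    Rm <- vapply(lags[bi], function(k) {
      shifted <- ref_env[((t_idx - 1L - k) %% Tn) + 1L]
      v <- shifted[keep]
      vc <- v - mean(v)
      nv <- sqrt(sum(vc^2))
      if (nv == 0) rep(0, length(v)) else vc / nv
    }, numeric(sum(keep)))
    r <- En %*% Rm
    max_stats[bi] <- pmax(apply(r, 2L, max), 0)
  }
  structure(list(max_stats = max_stats, lags = lags, n_perm = length(lags),
                 min_lag_s = min_lag_s, seed = seed, method = method),
            class = "permutation_null")
}

# Admissible circular lags: integer sample shifts whose circular distance to
# zero (and to every seam-induced offset) exceeds the exclusion span.
admissible_lags <- function(Tn, fs, min_lag_s, seg_bounds = integer(0)) {
  m <- min_lag_s * fs
  centers <- unique(c(0L, seg_bounds, Tn - seg_bounds))
  k <- seq_len(Tn - 1L)
  circ_d <- function(a, c) pmin((a - c) %% Tn, (c - a) %% Tn)
  ok <- rep(TRUE, length(k))
  for (c in centers) ok <- ok & circ_d(k, c) > m
  k[ok]
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d %s permutations, |lag| > %g s, max stat %.3f..%.3f\n",
              x$n_perm, x$method, x$min_lag_s, min(x$max_stats),
              max(x$max_stats)))
  invisible(x)
}

#' Family-wise-corrected significance map
#'
#' Thresholds the observed correlation map at the empirical `1 - alpha`
#' quantile of the permutation max statistics (upper order statistic,
#' `sorted[ceiling((1 - alpha) n)]`), controlling the family-wise error over
#' the whole solution space. A point is significant iff its correlation
#' strictly exceeds the threshold.
#'
#' @param map a [envelope_correlation_map()] result.
#' @param null a [build_null()] result built on the same field/reference pair.
#' @param alpha significance level in `(0, 0.5]` (default 0.01).
#' @return A `significance_map` tibble (`point`, `r`, `significant`) with
#'   `alpha` and `threshold_r` attributes.
#' @export
significance_map <- function(map, null, alpha = 0.01) {
  stopifnot(inherits(map, "correlation_map"),
            inherits(null, "permutation_null"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    stop("`alpha` must be in (0, 0.5]", call. = FALSE)
  }
  ms <- sort(null$max_stats)
  thr <- ms[ceiling((1 - alpha) * length(ms))]
  out <- tibble::tibble(point = map$point, r = map$r,
                        significant = map$r > thr)
  class(out) <- c("significance_map", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "threshold_r") <- thr
  out
}
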