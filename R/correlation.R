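#' Envelope correlation map against an intracranial reference
#'
#' Pearson correlation, at lag zero, between the reference envelope and the
#' reconstructed envelope at every solution point, using only frames outside
#' the filter-edge exclusion zone. Negative correlations are set to zero
#' (they can stem from the spatial thresholding step); the raw value is kept
#' in `r_raw` for diagnostics. Constant series yield an undefined correlation
#' and are stored as zero, with the count reported in the `n_zeroed`
#' attribute.
#'
#' @param field an [source_envelopes()] result (normally after
#'   [spatial_threshold()]).
#' @param ref_env numeric reference envelope on the field's time grid (see
#'   [ref_envelope()]).
#' @param ref_id optional label of the reference channel.
#' @return A `correlation_map` tibble: point index, coordinates, `r`
#'   (nonnegative) and `r_raw`; attributes `ref_id`, `n_samples`, `src`.
#' @export
envelope_correlation_map <- function(field, ref_env, ref_id = NULL) {
  stopifnot(inherits(field, "envelope_field"))
  if (length(ref_env) != ncol(field$env)) {
    stop("reference envelope and field must share a time base", call. = FALSE)
  }
  keep <- field$keep
  if (sum(keep) <= 2L) stop("fewer than 3 usable frames", call. = FALSE)
  E <- field$env[, keep, drop = FALSE]
  v <- ref_env[keep]
  r_raw <- row_cor(E, v, fill = NA_real_)
  n_zeroed <- sum(is.na(r_raw))
  if (n_zeroed > 0) {
    message(sprintf("%d point(s) with undefined correlation set to 0",
                    n_zeroed))
    r_raw[is.na(r_raw)] <- 0
  }
  out <- tibble::tibble(
    point = seq_len(nrow(E)),
    x = field$src$points[, 1],
    y = field$src$points[, 2],
    z = field$src$points[, 3],
    r = pmax(r_raw, 0),
    r_raw = r_raw
  )
  class(out) <- c("correlation_map", class(out))
  attr(out, "ref_id") <- ref_id
  attr(out, "n_samples") <- sum(keep)
  attr(out, "src") <- field$src
  attr(out, "n_zeroed") <- n_zeroed
  out
}

#' Cross-correlation as a function of time lag
#'
#' Pearson correlation between two series over integer-sample lags up to
#' `max_lag_s`, computed on the overlapping part at each lag. Positive lags
#' mean `b` is delayed relative to `a` (the curve peaks at the lag by which
#' `b` trails `a`).
#'
#' @param a,b numeric series of equal length on a common time base.
#' @param max_lag_s maximum absolute lag in seconds (< duration/4).
#' @param fs sampling rate of both series in Hz.
#' @return A `lag_curve` tibble with columns `lag` (samples), `lag_s` and `r`.
#' @export
cross_correlation_lags <- function(a, b, max_lag_s, fs) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant series have no defined correlation", call. = FALSE)
  }
  L <- floor(max_lag_s * fs)
  if (L >= n / 4) stop("`max_lag_s` must be below a quarter of the duration",
                       call. = FALSE)
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      stats::cor(a[1:(n - k)], b[(1 + k):n])
    } else {
      stats::cor(a[(1 - k):n], b[1:(n + k)])
    }
  }, 1.0)
  out <- tibble::tibble(lag = lags, lag_s = lags / fs, r = r)
  class(out) <- c("lag_curve", class(out))
  out
}

#' Correlation as a function of distance to the intracranial contact
#'
#' Bins the map's correlation values by Euclidean distance from the contact
#' and reports the per-bin mean and SD, the desk equivalent of
#' correlation-versus-distance profiles around the implanted electrode.
#'
#' @param map a [envelope_correlation_map()] result.
#' @param src the source space of the map.
#' @param contact length-3 contact position in mm.
#' @param bin_mm bin width in mm (default 4).
#' @param significant_only optional logical vector (e.g. from a significance
#'   map) restricting the profile to significant points; default all points.
#' @return A tibble with one row per bin: `bin_lo`, `bin_hi`, `mean_r`,
#'   `sd_r`, `n`. Empty bins have `n = 0` and `NA` statistics.
#' @export
distance_profile <- function(map, src, contact, bin_mm = 4,
                             significant_only = NULL) {
  stopifnot(inherits(map, "correlation_map"), inherits(src, "source_space"))
  assert_scalar_num(bin_mm, "bin_mm", lower = .Machine$double.eps)
  d <- sqrt(rowSums(sweep(src$points, 2L, as.numeric(contact))^2))
  r <- map$r
  if (!is.null(significant_only)) {
    d <- d[significant_only]
    r <- r[significant_only]
  }
  edges <- seq(0, max(d) + bin_mm, by = bin_mm)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  purrr::map_dfr(seq_len(length(edges) - 1L), function(k) {
    sel <- bin == k
    tibble::tibble(
      bin_lo = edges[k], bin_hi = edges[k + 1L], n = sum(sel),
      mean_r = if (any(sel)) mean(r[sel]) else NA_real_,
      sd_r = if (sum(sel) > 1L) stats::sd(r[sel]) else NA_real_
    )
  })
}

# Connected components of a set of solution points under 26-connectivity on
# the source grid.
grid_clusters <- function(src, members) {
  idx <- which(members)
  if (length(idx) == 0L) return(integer(0))
  gi <- src$grid_index[idx, , drop = FALSE]
  n <- length(idx)
  if (n == 1L) return(stats::setNames(1L, idx))
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) i < j), arr.ind = TRUE)
  che <- pmax(abs(gi[pairs[, 1], 1] - gi[pairs[, 2], 1]),
              abs(gi[pairs[, 1], 2] - gi[pairs[, 2], 2]),
              abs(gi[pairs[, 1], 3] - gi[pairs[, 2], 3]))
  e <- pairs[che <= 1L, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  stats::setNames(comp, idx)
}

#' Localization report against the true contact position
#'
#' Finds the connected cluster of significant points (26-connectivity on the
#' source grid) whose nearest member lies closest to the contact, takes that
#' cluster's correlation maximum as the localization estimate, and reports the
#' Euclidean distance from the contact to that maximum together with the
#' min-max contact-distance range spanned by the cluster's significant
#' points. With no significant point the report is marked not significant.
#'
#' @param map a [envelope_correlation_map()] result.
#' @param sig a [significance_map()] result for the same map.
#' @param src the source space.
#' @param contact length-3 true contact position in mm.
#' @return A one-row `localization_report` tibble: `significant`,
#'   `distance_mm`, `range_min_mm`, `range_max_mm`, peak coordinates, peak
#'   `r`, cluster size and the significance threshold.
#' @export
localization_report <- function(map, sig, src, contact) {
  stopifnot(inherits(map, "correlation_map"),
            inherits(sig, "significance_map"),
            inherits(src, "source_space"))
  contact <- as.numeric(contact)
  thr <- attr(sig, "threshold_r")
  sig_points <- sig$significant
  if (!any(sig_points)) {
    out <- tibble::tibble(
      significant = FALSE, distance_mm = NA_real_,
      range_min_mm = NA_real_, range_max_mm = NA_real_,
      peak_x = NA_real_, peak_y = NA_real_, peak_z = NA_real_,
      peak_r = NA_real_, cluster_size = 0L, threshold_r = thr
    )
    class(out) <- c("localization_report", class(out))
    return(out)
  }
  comp <- grid_clusters(src, sig_points)
  idx <- as.integer(names(comp))
  d_contact <- sqrt(rowSums(sweep(src$points[idx, , drop = FALSE], 2L,
                                  contact)^2))
  nearest_per_cluster <- tapply(d_contact, comp, min)
  chosen <- as.integer(names(which.min(nearest_per_cluster)))
  in_cluster <- comp == chosen
  members <- idx[in_cluster]
  peak <- members[which.max(map$r[members])]
  peak_pos <- src$points[peak, ]
  out <- tibble::tibble(
    significant = TRUE,
    distance_mm = sqrt(sum((peak_pos - contact)^2)),
    range_min_mm = min(d_contact[in_cluster]),
    range_max_mm = max(d_contact[in_cluster]),
    peak_x = peak_pos[1], peak_y = peak_pos[2], peak_z = peak_pos[3],
    peak_r = map$r[peak], cluster_size = sum(in_cluster), threshold_r = thr
  )
  class(out) <- c("localization_report", class(out))
  out
}

#' Robustness of the correlation map to the analysis window length
#'
#' Recomputes the correlation map in non-overlapping windows tiled from the
#' record start and summarizes, per window size, the correlation at the
#' full-record peak point (mean and SD across windows) and the spatial Pearson
#' correlation between each window's map and the full-length map.
#'
#' @param field an [source_envelopes()] result.
#' @param ref_env reference envelope on the field's time grid.
#' @param window_sizes numeric vector of window lengths in seconds.
#' @param min_frames minimum usable frames for a window to count (default 10).
#' @return A tibble with one row per window size: `window_s`, `n_windows`,
#'   `mean_r`, `sd_r`, `mean_map_similarity`, `min_map_similarity`. Per-window
#'   detail is kept in the `detail` attribute.
#' @export
window_robustness <- function(field, ref_env, window_sizes, min_frames = 10L) {
  stopifnot(inherits(field, "envelope_field"))
  dur <- ncol(field$env) / field$fs
  if (any(window_sizes > dur + 1e-9)) {
    stop("window longer than the record", call. = FALSE)
  }
  full <- envelope_correlation_map(field, ref_env)
  peak <- which.max(full$r)
  keep <- field$keep
  E <- field$env
  detail <- list()
  summarize_size <- function(w) {
    starts <- seq(0, dur - w + 1e-9, by = w)
    rows <- purrr::map_dfr(starts, function(t0) {
      in_win <- field$times >= t0 & field$times < t0 + w & keep
      if (sum(in_win) < min_frames) {
        return(tibble::tibble(window_s = w, t0 = t0, r_peak = NA_real_,
                              map_similarity = NA_real_))
      }
      rw <- pmax(row_cor(E[, in_win, drop = FALSE], ref_env[in_win]), 0)
      tibble::tibble(window_s = w, t0 = t0, r_peak = rw[peak],
                     map_similarity = suppressWarnings(stats::cor(rw, full$r)))
    })
    rows[!is.na(rows$r_peak), , drop = FALSE]
  }
  per_win <- purrr::map_dfr(window_sizes, summarize_size)
  out <- per_win |>
    dplyr::group_by(.data$window_s) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      mean_r = mean(.data$r_peak),
      sd_r = if (dplyr::n() > 1L) stats::sd(.data$r_peak) else 0,
      mean_map_similarity = mean(.data$map_similarity),
      min_map_similarity = min(.data$map_similarity),
      .groups = "drop"
    )
  attr(out, "detail") <- per_win
  attr(out, "peak_point") <- peak
  out
}
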