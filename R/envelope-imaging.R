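#' Source-space alpha amplitude envelopes
#'
#' Computes the analytic (Hilbert) signal of every sensor, inverts the real
#' and the imaginary part separately with the linear operator, forms the
#' complex current per Cartesian component at every solution point, takes the
#' magnitude per component, and combines the x/y/z components by the Euclidean
#' norm. Because the inverse is linear and time-pointwise, temporal
#' decimation commutes exactly with this construction, so the envelope field
#' is evaluated on a 25 Hz time grid by default (alpha envelopes are
#' band-limited far below that); set `decimate_to = NULL` for the full rate.
#'
#' @param op an [build_laura_operator()] inverse operator.
#' @param scalp_narrowband a band-passed, average-referenced [recording()]
#'   (output of [bandpass()] then [to_average_reference()] or vice versa).
#' @param decimate_to target envelope sampling rate in Hz (default 25), or
#'   `NULL`/`Inf` to keep the input rate.
#' @return An `envelope_field`: nonnegative `env` (points x frames), frame
#'   times, envelope sampling rate, the analysis band, a `keep` mask marking
#'   frames outside filter/Hilbert edge regions, and the source space.
#' @export
source_envelopes <- function(op, scalp_narrowband, decimate_to = 25) {
  stopifnot(inherits(op, "inverse_operator"),
            inherits(scalp_narrowband, "recording"))
  band <- attr(scalp_narrowband, "band")
  if (is.null(band)) {
    stop("input must be band-passed (missing band provenance)", call. = FALSE)
  }
  if (scalp_narrowband$reference != "average") {
    stop("input must be average-referenced", call. = FALSE)
  }
  fs <- scalp_narrowband$fs
  Z <- analytic_rows(scalp_narrowband$data)
  Tfull <- ncol(Z)
  k <- if (is.null(decimate_to) || !is.finite(decimate_to) ||
           decimate_to >= fs) 1L else max(1L, round(fs / decimate_to))
  idx <- seq(1L, Tfull, by = k)
  fs_env <- fs / k
  Z <- Z[, idx, drop = FALSE]
  cre <- op$G %*% Re(Z)
  cim <- op$G %*% Im(Z)
  S <- cre^2 + cim^2
  p <- op$n_points
  i1 <- seq(1L, 3L * p, by = 3L)
  env <- sqrt(S[i1, , drop = FALSE] + S[i1 + 1L, , drop = FALSE] +
                S[i1 + 2L, , drop = FALSE])
  times <- (idx - 1L) / fs
  edge <- attr(scalp_narrowband, "edge_excl_s") %||% 0
  keep <- times >= edge & times <= (Tfull - 1L) / fs - edge
  seg_bounds <- attr(scalp_narrowband, "seg_bounds")
  seg_bounds_env <- if (length(seg_bounds)) {
    unique(pmax(1L, round(seg_bounds / k)))
  } else {
    integer(0)
  }
  structure(list(env = env, fs = fs_env, times = times, keep = keep,
                 band = band, thresholded = FALSE, src = op$src,
                 seg_bounds = seg_bounds_env),
            class = "envelope_field")
}

#' @export
print.envelope_field <- function(x, ...) {
  cat(sprintf("<envelope_field> %d points x %d frames @ %g Hz%s\n",
              nrow(x$env), ncol(x$env), x$fs,
              if (x$thresholded) ", thresholded" else ""))
  invisible(x)
}

#' Spatial thresholding of an envelope field
#'
#' For every time frame, sets entries below that frame's spatial mean (over
#' all solution points) to exactly zero, limiting spatial leakage before the
#' correlation step. Entries equal to the mean are kept. Deliberately not
#' idempotent (the spatial mean of a thresholded frame differs), so applying
#' it twice is an error.
#'
#' @param field an [source_envelopes()] result with `thresholded = FALSE`.
#' @return The thresholded `envelope_field`.
#' @export
spatial_threshold <- function(field) {
  stopifnot(inherits(field, "envelope_field"))
  if (isTRUE(field$thresholded)) {
    stop("field is already thresholded; the operation is not idempotent",
         call. = FALSE)
  }
  mu <- colMeans(field$env)
  below <- sweep(field$env, 2L, mu, `<`)
  field$env[below] <- 0
  field$thresholded <- TRUE
  field
}

#' Aligned reference envelope for correlation with an envelope field
#'
#' Extracts one channel's envelope from a [analytic_envelope()] result and
#' subsamples it onto the time grid of an [source_envelopes()] field so the
#' two share a time base. Both recordings must have been acquired
#' synchronously at the same sampling rate.
#'
#' @param envs a `channel_envelopes` object.
#' @param channel channel label or index.
#' @param field the `envelope_field` defining the target time grid.
#' @return Numeric envelope vector with one value per field frame.
#' @export
ref_envelope <- function(envs, channel, field) {
  stopifnot(inherits(envs, "channel_envelopes"),
            inherits(field, "envelope_field"))
  i <- if (is.numeric(channel)) channel else match(channel, envs$labels)
  if (is.na(i)) stop("unknown channel", call. = FALSE)
  idx <- round(field$times * envs$fs) + 1L
  if (max(idx) > ncol(envs$env)) {
    stop("field time grid extends beyond the reference recording",
         call. = FALSE)
  }
  envs$env[i, idx]
}

#' Rasterize a per-point map onto a regular volume grid
#'
#' Nearest-point rasterization of per-solution-point values onto a regular
#' grid (default 4 mm), for viewing correlation maps as volumes. The returned
#' array carries the grid coordinates as attributes and can be written with
#' `RNifti::writeNifti()` if NIfTI output is wanted.
#'
#' @param values numeric vector, one value per solution point.
#' @param src the [build_source_space()] the values live on.
#' @param grid_mm voxel size in mm (default 4).
#' @return 3-D array of voxel values (NA outside the source space).
#' @export
rasterize_map <- function(values, src, grid_mm = 4) {
  stopifnot(inherits(src, "source_space"),
            length(values) == nrow(src$points))
  rng <- apply(src$points, 2L, range)
  ax <- lapply(1:3, function(k) seq(rng[1, k], rng[2, k], by = grid_mm))
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  nn <- apply(vox, 1L, function(v) {
    d2 <- rowSums(sweep(src$points, 2L, v)^2)
    j <- which.min(d2)
    if (d2[j] <= (1.5 * src$spacing)^2) j else NA_integer_
  })
  out <- array(ifelse(is.na(nn), NA_real_, values[nn]),
               dim = vapply(ax, length, 1L))
  attr(out, "grid_mm") <- grid_mm
  attr(out, "origin") <- vapply(ax, min, 1)
  out
}
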