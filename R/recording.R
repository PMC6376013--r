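#' Multichannel electrophysiological recording
#'
#' Container for a block of synchronized channels: a channels x samples matrix
#' in microvolts together with the sampling rate, channel labels, optional 3-D
#' channel positions (mm, head-centred RAS) and the referencing state.
#'
#' @param data numeric matrix, channels x samples, in uV.
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel names (defaults to `ch1`, ...).
#' @param positions optional numeric matrix (channels x 3) of positions in mm.
#' @param reference referencing state: `"vertex"`, `"mastoid"`, `"raw"`,
#'   `"average"` or `"bipolar"`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL, positions = NULL,
                      reference = c("raw", "vertex", "mastoid", "average",
                                    "bipolar")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (anyNA(data)) stop("`data` must not contain NA values", call. = FALSE)
  assert_scalar_num(fs, "fs", lower = .Machine$double.eps)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("`labels` length must equal the number of channels", call. = FALSE)
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3L) {
      stop("`positions` must be a channels x 3 matrix", call. = FALSE)
    }
    dimnames(positions) <- NULL
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, positions = positions,
         reference = reference),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  if (!is.null(attr(x, "band"))) {
    b <- attr(x, "band")
    cat(sprintf("  band-passed: %.2f-%.2f Hz\n", b[1], b[2]))
  }
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean over all channels from every channel, the
#' offline average-reference recalculation conventionally applied to
#' high-density scalp EEG before source analysis. Idempotent: applying it to
#' already average-referenced data leaves it unchanged.
#'
#' @param rec a [recording()] with at least two channels, referenced to a
#'   single electrode (vertex/mastoid) or raw.
#' @return A `recording` with `reference = "average"` and zero channel mean at
#'   every sample.
#' @export
to_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$reference == "bipolar") {
    stop("cannot average-reference bipolar data", call. = FALSE)
  }
  if (nrow(rec$data) < 2L) {
    stop("average reference requires at least 2 channels", call. = FALSE)
  }
  out <- rec
  out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  out$reference <- "average"
  attributes(out$data) <- attributes(rec$data)
  rownames(out$data) <- rec$labels
  for (a in c("band", "edge_excl_s", "seg_bounds")) {
    attr(out, a) <- attr(rec, a)
  }
  out
}

#' Recalculate contact recordings to bipolar derivations
#'
#' Adjacent-contact differences along each intracranial lead, suppressing
#' far-field signals common to neighbouring contacts. The sign convention is
#' deeper contact minus shallower contact; contacts must be listed from the
#' deepest to the shallowest within each lead. Each bipolar channel is placed
#' at the midpoint of its contact pair.
#'
#' @param rec a [recording()] holding the contact signals.
#' @param lead_layout named list; each element is the ordered (deep to
#'   shallow) character vector of contact labels of one lead.
#' @return A `recording` with `n - 1` bipolar channels per `n`-contact lead,
#'   labelled `"<deep>-<shallow>"`. Lead membership is kept in the
#'   `lead_layout` attribute.
#' @export
to_bipolar <- function(rec, lead_layout) {
  stopifnot(inherits(rec, "recording"), is.list(lead_layout))
  all_contacts <- unlist(lead_layout, use.names = FALSE)
  missing <- setdiff(all_contacts, rec$labels)
  if (length(missing) > 0L) {
    stop("unknown lead contacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(lead_layout, length, 1L) < 2L)) {
    stop("each lead needs at least 2 contacts", call. = FALSE)
  }
  rows <- list(); labs <- character(); pos <- list(); membership <- list()
  for (lead in names(lead_layout)) {
    contacts <- lead_layout[[lead]]
    idx <- match(contacts, rec$labels)
    for (j in seq_len(length(contacts) - 1L)) {
      rows[[length(rows) + 1L]] <- rec$data[idx[j], ] - rec$data[idx[j + 1L], ]
      lab <- paste0(contacts[j], "-", contacts[j + 1L])
      labs <- c(labs, lab)
      membership[[lead]] <- c(membership[[lead]], lab)
      if (!is.null(rec$positions)) {
        pos[[length(pos) + 1L]] <-
          (rec$positions[idx[j], ] + rec$positions[idx[j + 1L], ]) / 2
      }
    }
  }
  out <- recording(do.call(rbind, rows), rec$fs, labels = labs,
                   positions = if (length(pos)) do.call(rbind, pos) else NULL,
                   reference = "bipolar")
  attr(out, "lead_layout") <- membership
  out
}

#' Retain artifact-free segments of a recording
#'
#' Concatenates the samples falling in the supplied keep-intervals. Artifact
#' detection itself is out of scope; intervals come from upstream (visual or
#' automated) screening. Segment boundaries are recorded in the `seg_bounds`
#' attribute (sample offsets of each seam in the concatenated record) so that
#' downstream lag-based statistics can avoid drawing lags that straddle a
#' seam. A `below_min_duration` attribute flags totals under `min_total_s`.
#'
#' @param rec a [recording()].
#' @param keep_intervals list of `c(t0, t1)` half-open intervals in seconds,
#'   non-overlapping and within the record.
#' @param min_total_s minimum total retained duration before a warning is
#'   raised (default 240 s, i.e. 4 minutes).
#' @return A `recording` of the concatenated retained samples.
#' @export
select_segments <- function(rec, keep_intervals, min_total_s = 240) {
  stopifnot(inherits(rec, "recording"), is.list(keep_intervals))
  dur <- duration_s(rec)
  iv <- do.call(rbind, lapply(keep_intervals, function(x) {
    if (length(x) != 2L || x[2] <= x[1]) {
      stop("each interval must be c(t0, t1) with t1 > t0", call. = FALSE)
    }
    x
  }))
  if (any(iv[, 1] < 0) || any(iv[, 2] > dur + 1e-9)) {
    stop("keep interval outside the record", call. = FALSE)
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2] - 1e-12)) {
    stop("keep intervals overlap", call. = FALSE)
  }
  idx <- integer(); bounds <- integer()
  for (k in seq_len(nrow(iv))) {
    i0 <- floor(iv[k, 1] * rec$fs) + 1L
    i1 <- min(ceiling(iv[k, 2] * rec$fs), n_samples(rec))
    idx <- c(idx, i0:i1)
    if (k < nrow(iv)) bounds <- c(bounds, length(idx))
  }
  out <- recording(rec$data[, idx, drop = FALSE], rec$fs, rec$labels,
                   rec$positions,
                   reference = rec$reference)
  attr(out, "lead_layout") <- attr(rec, "lead_layout")
  attr(out, "seg_bounds") <- bounds
  total_s <- length(idx) / rec$fs
  below <- total_s < min_total_s
  attr(out, "below_min_duration") <- below
  if (below) {
    warning(sprintf("retained %.1f s, below the %g s minimum", total_s,
                    min_total_s), call. = FALSE)
  }
  out
}
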