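#' Write a session to plain-text files
#'
#' Persists a (typically simulated) session as a documented plain-text layout:
#' tab-separated data matrices (samples x channels, uV, full double
#' precision), `.sfp`-style whitespace montage files (`label x y z`, mm,
#' head-centred RAS), a ground-truth JSON sidecar and a `meta.json` with
#' sampling rate, units, reference state and lead layout.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rec <- function(rec, stem) {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$labels
    utils::write.table(format(df, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       file.path(dir, paste0(stem, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(rec$positions)) {
      sfp <- data.frame(label = rec$labels, rec$positions)
      utils::write.table(sfp, file.path(dir, paste0(stem, ".sfp")),
                         sep = " ", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  }
  write_rec(session$scalp, "scalp")
  write_rec(session$intracranial, "intracranial")
  meta <- list(
    fs = session$scalp$fs, units = "uV",
    scalp_reference = session$scalp$reference,
    intracranial_reference = session$intracranial$reference,
    lead_layout = attr(session$intracranial, "lead_layout")
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  truth <- session$truth
  truth$contact_positions <- lapply(truth$contact_positions, unname)
  jsonlite::write_json(
    list(source_positions = unname(truth$source_positions),
         source_freqs = truth$source_freqs,
         contact_positions = truth$contact_positions,
         deep_idx = truth$deep_idx),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a session from plain-text files
#'
#' Counterpart of [write_session()]: reads the TSV data matrices, montage
#' files and metadata, verifies channel/montage consistency, and converts
#' units to microvolts when the metadata declares millivolts (logged via a
#' message).
#'
#' @param dir directory written by [write_session()] (or assembled by hand in
#'   the same layout).
#' @return List with `scalp` and `intracranial` [recording()]s, the `contacts`
#'   positions (from the intracranial montage) and the ground `truth` when a
#'   `truth.json` sidecar is present.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  scale <- 1
  if (!is.null(meta$units) && tolower(meta$units) == "mv") {
    scale <- 1000
    message("units declared in mV; converting to uV")
  }
  read_rec <- function(stem, reference) {
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    if (!file.exists(tsv)) stop("missing ", stem, ".tsv", call. = FALSE)
    df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            check.names = FALSE)
    data <- t(as.matrix(df)) * scale
    labels <- colnames(df)
    sfp <- file.path(dir, paste0(stem, ".sfp"))
    positions <- NULL
    if (file.exists(sfp)) {
      mt <- utils::read.table(sfp, header = FALSE)
      if (nrow(mt) != length(labels) || !all(mt[[1]] == labels)) {
        stop("montage does not match the channels of ", stem, call. = FALSE)
      }
      positions <- as.matrix(mt[, 2:4])
      dimnames(positions) <- NULL
    }
    recording(data, meta$fs, labels = labels, positions = positions,
              reference = reference)
  }
  scalp <- read_rec("scalp", meta$scalp_reference %||% "raw")
  intracranial <- read_rec("intracranial",
                           meta$intracranial_reference %||% "mastoid")
  if (!is.null(meta$lead_layout)) {
    attr(intracranial, "lead_layout") <- lapply(meta$lead_layout, unlist)
  }
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  list(scalp = scalp, intracranial = intracranial,
       contacts = intracranial$positions, truth = truth)
}
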