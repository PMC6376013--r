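#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power spectrum into a long tibble
#'
#' @param x a `power_spectrum`.
#' @param ... unused.
#' @return Tibble with columns `channel`, `freq`, `power`.
#' @method tidy power_spectrum
#' @export
tidy.power_spectrum <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(cbind(data.frame(freq = x$freqs),
                            as.data.frame(x$power))),
    -"freq", names_to = "channel", values_to = "power"
  ) |>
    dplyr::arrange(.data$channel, .data$freq)
}

#' @method tidy correlation_map
#' @export
tidy.correlation_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method tidy significance_map
#' @export
tidy.significance_map <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$threshold_r <- attr(x, "threshold_r")
  out
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$max_stats), lag = x$lags,
                 max_r = x$max_stats)
}

#' @method tidy channel_envelopes
#' @export
tidy.channel_envelopes <- function(x, ...) {
  df <- tibble::as_tibble(cbind(data.frame(time = (seq_len(ncol(x$env)) - 1) /
                                             x$fs),
                                as.data.frame(t(x$env))))
  tidyr::pivot_longer(df, -"time", names_to = "channel",
                      values_to = "envelope")
}

#' One-row summaries per lead of a pipeline run
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return Tibble with one row per intracranial lead: whether an alpha peak
#'   was found, localization distance, significant range and peak correlation.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  if (is.null(x$reports)) {
    return(tibble::tibble(lead = names(x$refs), peak_found = FALSE))
  }
  x$reports
}

#' @method glance localization_report
#' @export
glance.localization_report <- function(x, ...) tibble::as_tibble(x)
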