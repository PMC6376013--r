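#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a power spectrum
#'
#' Log-power spectral density per channel, with an optional highlighted band.
#'
#' @param object a `power_spectrum`.
#' @param band optional `alpha_band` or numeric `c(lo, hi)` to shade.
#' @param channels optional subset of channel labels.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, band = NULL, channels = NULL,
                                    ...) {
  df <- tidy(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                        group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
  if (inherits(band, "alpha_band")) band <- band$band
  if (!is.null(band) && all(is.finite(band))) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p
}

#' Plot a correlation map as orthogonal scatter projections
#'
#' Each solution point is drawn in its axial (x-y) projection, coloured by
#' correlation; significant points (if a significance map is given) are
#' outlined.
#'
#' @param object a `correlation_map`.
#' @param sig optional `significance_map` for the same map.
#' @param contact optional length-3 contact position to mark.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot correlation_map
#' @export
autoplot.correlation_map <- function(object, sig = NULL, contact = NULL,
                                     ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$r)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "r")
  if (!is.null(sig)) {
    hot <- df[sig$significant, , drop = FALSE]
    if (nrow(hot) > 0) {
      p <- p + ggplot2::geom_point(data = hot, shape = 21, size = 2,
                                   colour = "cyan", fill = NA)
    }
  }
  if (!is.null(contact)) {
    p <- p + ggplot2::annotate("point", x = contact[1], y = contact[2],
                               shape = 4, size = 4, colour = "blue")
  }
  p
}

#' Plot a cross-correlation lag curve
#'
#' @param object a `lag_curve` from [cross_correlation_lags()].
#' @param min_lag_s optional exclusion bound to mark (e.g. 2 s).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot lag_curve
#' @export
autoplot.lag_curve <- function(object, min_lag_s = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Lag (s)", y = "r")
  if (!is.null(min_lag_s)) {
    p <- p + ggplot2::geom_vline(xintercept = c(-1, 1) * min_lag_s,
                                 linetype = 2, colour = "grey50")
  }
  p
}

#' Plot correlation versus distance to the intracranial contact
#'
#' @param profile a [distance_profile()] tibble.
#' @return A ggplot of per-bin mean with an SD ribbon.
#' @export
plot_distance_profile <- function(profile) {
  df <- dplyr::filter(profile, .data$n > 0)
  mid <- (df$bin_lo + df$bin_hi) / 2
  df$mid <- mid
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_r - dplyr::coalesce(.data$sd_r, 0),
      ymax = .data$mean_r + dplyr::coalesce(.data$sd_r, 0)), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance to contact (mm)", y = "Mean r")
}
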