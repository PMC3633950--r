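#' Plot a transfer-efficiency map
#'
#' Renders the correlation-time by order-parameter map with the
#' conventional colour code: INEPT in red, CP in blue, white where neither
#' scheme transfers polarization.
#'
#' @param object An [efficiency_map()].
#' @param normalization `"per_scheme"` (each channel scaled to its own
#'   maximum) or `"joint"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efficiency_map
#' @export
autoplot.efficiency_map <- function(object, normalization = c("per_scheme", "joint"),
                                    ...) {
  normalization <- match.arg(normalization)
  df <- as_tibble(object)
  if (normalization == "per_scheme") {
    cp <- df$i_cp / max(df$i_cp)
    inept <- df$i_inept / max(df$i_inept)
  } else {
    m <- max(df$i_cp, df$i_inept)
    cp <- df$i_cp / m
    inept <- df$i_inept / m
  }
  df$fill <- grDevices::rgb(1 - cp, 1 - cp - inept + cp * inept, 1 - inept)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_c, y = .data$order_parameter)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau[c] ~ "(s)"), y = expression("|" * S[CH] * "|"),
                  title = "Polarization-transfer efficiency (CP blue, INEPT red)") +
    ggplot2::theme_minimal()
}

#' Overlay the DP/CP/INEPT spectra of a triplet
#'
#' Standard colour code: DP grey, CP blue, INEPT red.
#'
#' @param triplet A [spectrum_triplet()].
#' @param xlim Optional ppm range (plotted right-to-left).
#' @return A ggplot object.
#' @export
plot_triplet <- function(triplet, xlim = NULL) {
  stopifnot(inherits(triplet, "spectrum_triplet"))
  df <- dplyr::bind_rows(
    tibble(ppm = triplet$dp$ppm, intensity = triplet$dp$intensity, scheme = "DP"),
    tibble(ppm = triplet$cp$ppm, intensity = triplet$cp$intensity, scheme = "CP"),
    tibble(ppm = triplet$inept$ppm, intensity = triplet$inept$intensity,
           scheme = "INEPT"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity,
                                        colour = .data$scheme)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(DP = "grey40", CP = "blue3",
                                            INEPT = "red3")) +
    ggplot2::scale_x_reverse(limits = if (is.null(xlim)) NULL else rev(sort(xlim))) +
    ggplot2::labs(x = "13C chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
  p
}

#' Colour-coded dynamic-state summary of a series
#'
#' Tile plot of per-window state calls along the series variable, using the
#' rigid = blue / mobile = red convention.
#'
#' @param object A [series_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot series_report
#' @export
autoplot.series_report <- function(object, ...) {
  df <- object$calls
  pal <- c(mobile_isotropic = "red3", mobile_anisotropic = "orange2",
           rigid_slow = "blue3", intermediate = "grey70",
           ambiguous = "grey90")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[object$by]]),
                                   y = .data$moiety,
                                   fill = .data$state_call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = object$by, y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' @method autoplot nmr_spectrum
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "13C chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
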