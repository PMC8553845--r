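#' Contour rendering of an acuity map
#'
#' Equirectangular visualisation (azimuth horizontal, elevation vertical)
#' of the `dphi_mean` field with labelled iso-delta-phi contours.  Purely
#' a visualisation aid; never an analysis input.
#'
#' @param map An `"acuity_map"`.
#' @param levels_deg Contour levels in degrees.
#' @param field Node column to draw.
#' @return A ggplot object.
#' @export
plot_map <- function(map, levels_deg = c(1.5, 1.7, 1.9, 2.0, 2.5),
                     field = "dphi_mean_deg") {
  stopifnot(inherits(map, "acuity_map"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the 'ggplot2' package", call. = FALSE)
  }
  nd <- map$nodes[map$nodes$valid, , drop = FALSE]
  nd$z <- nd[[field]]
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$azimuth_deg,
                                   y = .data$elevation_deg)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), breaks = levels_deg,
                          colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * varphi ~ (deg)),
                                  direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Azimuth (deg)", y = "Elevation (deg)")
}
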