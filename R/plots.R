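ring_data <- function(radii) {
  purrr::map_dfr(radii, function(r) {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(r = r, x = r * cos(th), y = r * sin(th))
  })
}

#' Plot a visual-field coverage map
#'
#' Raster of coverage density in visual-field coordinates with
#' eccentricity rings (2.4, 4.7 and 7 dva by default).
#'
#' @param object A `coverage_map`.
#' @param rings Eccentricity ring radii, dva.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coverage_map <- function(object, rings = c(2.4, 4.7, 7), ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_path(data = ring_data(rings),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$r),
                       inherit.aes = FALSE, colour = "white",
                       linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), name = "coverage") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (dva)", y = "y (dva)") +
    ggplot2::theme_minimal()
}

#' Plot a fixation-density map
#'
#' Raster of fixation density in screen coordinates (y increases
#' downward, as on the screen).
#'
#' @param object A `density_map`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.density_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Scatter of pRF size against eccentricity with the weighted fit
#'
#' @param fits pRF fit tibble (`ecc`, `size`, `ve`).
#' @param ve_min Fit threshold passed to [size_ecc_fit()].
#' @return A ggplot object.
#' @export
plot_size_ecc <- function(fits, ve_min = 0.05) {
  f <- size_ecc_fit(fits, ve_min = ve_min)
  ggplot2::ggplot(dplyr::filter(fits, .data$ve > ve_min),
                  ggplot2::aes(x = .data$ecc, y = .data$size)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$ve), size = 1) +
    ggplot2::geom_abline(slope = f$slope, intercept = f$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "eccentricity (dva)", y = "pRF size (dva)",
                  alpha = "ve") +
    ggplot2::theme_minimal()
}

#' Plot fixation bias vectors
#'
#' Bias vectors from the adult centre to the child centre in
#' visual-field convention (y up), one arrow per stimulus.
#'
#' @param vectors Tibble of [bias_vector()] rows.
#' @return A ggplot object.
#' @export
plot_bias_vectors <- function(vectors) {
  ggplot2::ggplot(vectors) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$dx,
                                       yend = .data$dy),
                          arrow = ggplot2::arrow(length =
                                                   ggplot2::unit(2, "mm"))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dx (px, rightward)", y = "dy (px, upward)") +
    ggplot2::theme_minimal()
}
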