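#' Plot an embedding on the hyperbolic disk
#'
#' Polar scatter of the node coordinates: angle = `theta`, distance from the
#' plot center = `r`. Points can be colored by the angular coordinate (the
#' default, which makes angular coalescence visible) or by any column of the
#' coordinate tibble.
#'
#' @param object A `hyper_embedding` or `pso_network` object.
#' @param colour_by Column of the coordinate table used for the point color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyper_embedding <- function(object, colour_by = "theta", ...) {
  plot_disk(tidy(object), colour_by)
}

#' @rdname autoplot.hyper_embedding
#' @export
autoplot.pso_network <- function(object, colour_by = "theta", ...) {
  plot_disk(tidy(object), colour_by)
}

plot_disk <- function(coords, colour_by) {
  stopifnot(colour_by %in% names(coords))
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$theta, y = .data$r,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi),
                                breaks = c(0, pi / 2, pi, 3 * pi / 2),
                                labels = c("0", "π/2", "π", "3π/2")) +
    ggplot2::labs(x = NULL, y = "r") +
    ggplot2::theme_minimal()
}
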