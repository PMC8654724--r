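#' Plot methods
#'
#' `autoplot.tessellation()` draws the 2D cell polygons colored by
#' density (1D: density per cell center); `autoplot.grid_field()` draws
#' the macro density as a line (1D) or raster (2D);
#' `plot_density_comparison()` overlays micro samples on a macro
#' profile along a line.
#'
#' @param object a `tessellation` or `grid_field`.
#' @param ... unused.
#' @return a ggplot object.
#' @name cellgrain-plots
NULL

#' @rdname cellgrain-plots
#' @export
autoplot.tessellation <- function(object, ...) {
  if (object$d == 1) {
    ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$x, y = .data$rho)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(ggplot2::aes(shape = .data$boundary)) +
      ggplot2::labs(x = "x", y = expression(rho)) +
      ggplot2::theme_minimal()
  } else {
    polys <- dplyr::bind_rows(lapply(seq_along(object$polygons), function(k) {
      p <- object$polygons[[k]]
      tibble(cell = k, x = p[, 1], y = p[, 2],
             rho = object$cells$rho[k])
    }))
    ggplot2::ggplot(polys,
                    ggplot2::aes(x = .data$x, y = .data$y,
                                 group = .data$cell, fill = .data$rho)) +
      ggplot2::geom_polygon(color = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = expression(rho)) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
}

#' @rdname cellgrain-plots
#' @export
autoplot.grid_field <- function(object, ...) {
  td <- tidy(object)
  if (object$grid$d == 1) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$rho)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "x", y = expression(rho)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$rho)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = expression(rho)) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
}

#' @rdname cellgrain-plots
#' @param micro tibble of per-cell density samples.
#' @param field a `grid_field`.
#' @param y line coordinate for 2D fields.
#' @export
plot_density_comparison <- function(micro, field, y = NULL) {
  if (field$grid$d == 1) {
    macro <- tidy(field)
    mi <- micro
  } else {
    if (is.null(y)) y <- mean(range(field$grid$centers$y))
    macro <- line_profile(field, y)
    band <- 0.75 * field$grid$dx[2]
    mi <- micro[abs(micro$y - y) <= band, ]
  }
  ggplot2::ggplot() +
    ggplot2::geom_line(data = mi,
                       ggplot2::aes(x = .data$x, y = .data$rho,
                                    color = "micro")) +
    ggplot2::geom_point(data = macro,
                        ggplot2::aes(x = .data$x, y = .data$rho,
                                     color = "macro"), shape = 8) +
    ggplot2::scale_color_manual(NULL,
                                values = c(micro = "firebrick",
                                           macro = "steelblue")) +
    ggplot2::labs(x = "x", y = expression(rho)) +
    ggplot2::theme_minimal()
}
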