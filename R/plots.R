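#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a multiview ground-cover image
#'
#' @param object An [mv_image()].
#' @param ... Unused.
#' @return A ggplot raster of plant-pixel fractions.
#' @export
autoplot.mv_image <- function(object, ...) {
  d <- tibble::tibble(
    x = rep(seq_len(ncol(object$values)), each = nrow(object$values)),
    y = rep(seq_len(nrow(object$values)), times = ncol(object$values)),
    fraction = as.vector(object$values)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "plot x (px)", y = "plot y (px)",
                  fill = "plant-pixel\nfraction",
                  title = paste("Plot", object$plot_id, "-", object$n_views,
                                "views"))
}

#' Plot ground-cover percentile trajectories
#'
#' @param data A long tibble with columns `gdd` (or `dgdd`), `threshold`,
#'   `mvgc` (e.g. stacked [gc_percentiles()] output).
#' @return A ggplot of percentile trajectories over thermal time.
#' @export
plot_gc_percentiles <- function(data) {
  xvar <- if ("dgdd" %in% names(data)) "dgdd" else "gdd"
  ggplot2::ggplot(data, ggplot2::aes(.data[[xvar]], .data$mvgc,
                                     colour = factor(.data$threshold))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(if (xvar == "dgdd") "Δ" else "",
                             "GDD (°C·day)"),
                  y = "multiview ground cover", colour = "threshold (%)")
}

#' Plot a shoot-dynamics fit over its data
#'
#' @param object A [fit_shoot_dynamics()] result.
#' @param data The tibble the model was fitted to (`n_s_t`, `dgdd`).
#' @param ... Unused.
#' @return A ggplot with data points and the fitted (clamped) curve.
#' @export
autoplot.shoot_dynamics <- function(object, data, ...) {
  grid <- tibble::tibble(dgdd = seq(min(data$dgdd), max(data$dgdd),
                                    length.out = 100))
  grid$n_s_t <- predict_shoots(object, grid$dgdd)
  ggplot2::ggplot(data, ggplot2::aes(.data$dgdd, .data$n_s_t)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "tomato") +
    ggplot2::labs(x = "ΔGDD GS30 (°C·day)", y = "shoots")
}

#' Plot the fitted spatial surface of a correction result
#'
#' @param object A [spatial_correct()] result.
#' @param design The field design used for the fit (columns `plot_id`,
#'   `x`, `y`).
#' @param ... Unused.
#' @return A ggplot tile map of the fitted surface value per plot.
#' @export
autoplot.correction_result <- function(object, design, ...) {
  d <- dplyr::inner_join(object$data,
                         dplyr::select(design, "plot_id", "x", "y"),
                         by = "plot_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$surface)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "spatial\ntrend")
}
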