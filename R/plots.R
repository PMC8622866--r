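# ggplot2 views of the result types.

#' Plot a connectivity-length time series
#'
#' @param lc Tibble from [lc_timeseries()].
#' @return A ggplot object.
#' @export
plot_lc_timeseries <- function(lc) {
  ggplot2::ggplot(lc, ggplot2::aes(x = .data$frame, y = .data$lc)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "connectivity length") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.zincagg_composition <- function(object, ...) {
  df <- tidy(object) %>% dplyr::count(.data$size)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "complex size (molecule units)", y = "count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.zincagg_landscape <- function(object, ...) {
  df <- tidy(object) %>% filter(!is.na(.data$free_energy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$free_energy * object$kT)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "F (kT)") +
    ggplot2::labs(x = object$x_name, y = object$y_name) +
    ggplot2::theme_minimal()
}
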