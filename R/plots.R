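grid_to_tibble <- function(grid, value_name = "value") {
  idx <- which(!is.na(grid), arr.ind = TRUE)
  out <- tibble::tibble(row = idx[, 1], col = idx[, 2], value = grid[idx])
  names(out)[3] <- value_name
  out
}

#' Plot a suitability surface
#'
#' @param object a `suitability_surface`.
#' @param ... unused.
#' @return a ggplot raster map of suitability (row 1 at the top).
#' @export
autoplot.suitability_surface <- function(object, ...) {
  df <- grid_to_tibble(object$grid, "suitability")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s)", object$species, object$scenario),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a binary range
#'
#' @param object a `binary_range`.
#' @param ... unused.
#' @return a ggplot map of the thresholded, MESS-masked range.
#' @export
autoplot.binary_range <- function(object, ...) {
  df <- grid_to_tibble(object$grid * 1, "suitable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$suitable))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "darkgreen"),
                               name = "suitable") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s), threshold %.3f",
                                  object$species, object$scenario,
                                  object$threshold),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the elevation and islands of a generated landscape
#'
#' @param object a `climate_stack`.
#' @param ... unused.
#' @return a ggplot elevation map (valid cells only).
#' @export
autoplot.climate_stack <- function(object, ...) {
  g <- object$elevation
  g[!object$valid_mask] <- NA
  df <- grid_to_tibble(g, "elevation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$elevation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "cividis") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Percent-remaining overview plot
#'
#' @param report a range-change report tibble (see [run_pipeline()]),
#'   typically filtered to one region.
#' @return a ggplot dot plot of percent suitable area remaining per species
#'   and scenario.
#' @export
plot_range_change <- function(report) {
  df <- dplyr::filter(report, !is.na(.data$pct_remaining))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_remaining, y = .data$species,
                                   colour = .data$scenario)) +
    ggplot2::geom_vline(xintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "% suitable area remaining", y = NULL) +
    ggplot2::theme_minimal()
}
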