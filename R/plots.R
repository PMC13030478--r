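#' Plot a raster layer
#'
#' @param object an `inv_raster`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.inv_raster <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (object$kind == "categorical") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_viridis_d(name = "class", na.value = "grey90")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
}

#' @export
autoplot.zone_classification <- function(object, ...) {
  autoplot(object$zones) +
    ggplot2::scale_fill_viridis_d(name = "zone", labels = object$labels,
                                  na.value = "grey90")
}

#' @export
autoplot.maxent_sdm <- function(object, ...) {
  autoplot(object$hsi) +
    ggplot2::labs(title = paste("Habitat suitability:", object$species),
                  fill = "HSI")
}

#' @export
autoplot.detector_report <- function(object, ...) {
  ggplot2::ggplot(object$factor,
                  ggplot2::aes(x = stats::reorder(.data$factor, .data$q),
                               y = .data$q)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "q statistic") +
    ggplot2::theme_minimal()
}

#' Plot the priority map with protected areas overlaid
#'
#' @param priority a `priority_map`.
#' @param pas optional `inv_vector` of protected-area polygons.
#' @return a ggplot.
#' @export
plot_priority <- function(priority, pas = NULL) {
  p <- autoplot(priority$map) +
    ggplot2::scale_fill_manual(
      name = NULL, na.value = "grey90",
      values = c("0" = "grey95", "1" = "#74add1", "2" = "#fdae61",
                 "3" = "#d73027"),
      labels = c("none", "suitability only", "vulnerability only", "core"))
  if (!is.null(pas) && length(pas$features)) {
    polys <- dplyr::bind_rows(lapply(seq_along(pas$features), function(i) {
      sh <- pas$features[[i]]$coords[[1]]
      tibble::tibble(x = sh[, 1], y = sh[, 2], id = i)
    }))
    p <- p + ggplot2::geom_path(data = polys,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             group = .data$id),
                                colour = "black", linewidth = 0.3)
  }
  p
}
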