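# ggplot2 visualisation of rasters, detections and census results.

#' Plot a thermal raster
#'
#' Temperature heat map in world coordinates (equal aspect).
#'
#' @param object A [thermal_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermal_raster
#' @export
autoplot.thermal_raster <- function(object, ...) {
  df <- pixel_centers(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$temp_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey60",
                                  name = "°C") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

detections_to_df <- function(detections) {
  if (nrow(detections) == 0L)
    return(tibble::tibble(x = numeric(), y = numeric(), id = integer(),
                          ring = integer(), label = character()))
  purrr::pmap_dfr(
    list(detections$id, detections$label, detections$geometry),
    function(id, label, rings) {
      purrr::imap_dfr(rings, function(r, k)
        tibble::tibble(x = r[, 1], y = r[, 2], id = id, ring = k,
                       label = label %||% NA_character_))
    })
}

#' Plot census detections
#'
#' Draws the individual prediction polygons coloured by class, with
#' unclassified polygons (if any) in grey.
#'
#' @param object A `seal_census` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seal_census
#' @export
autoplot.seal_census <- function(object, ...) {
  df <- detections_to_df(dplyr::bind_rows(object$detections,
                                          object$unclassified))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = interaction(.data$id, .data$ring),
                                   fill = .data$label)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      individual_yoy = "#d73027", individual_adult = "#1a9850",
      unclassified = "grey70"), na.value = "grey70", name = "class") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its ground truth
#'
#' Heat map of the scene raster overlaid with the truth points.
#'
#' @param scene Result of [generate_scene()].
#' @return A ggplot.
#' @export
plot_scene <- function(scene) {
  autoplot.thermal_raster(scene$raster) +
    ggplot2::geom_point(data = scene$truth$points,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$label),
                        colour = "cyan", size = 1.5, inherit.aes = FALSE)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
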