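# Splitting aggregation polygons into individual seals. Inside a merged
# footprint the continuous temperatures still carry structure: each animal
# is a local warm core and the contact lines between bodies are cool
# seams. A zero-sum high-pass response is therefore positive over bodies
# and negative along seams; thresholding the response inside the footprint
# and re-clustering yields one component per animal.

#' Split one aggregation polygon into individual seals
#'
#' Within the aggregation's footprint, cells whose high-pass response
#' exceeds `response_min` (default 0, the flat-background level of a
#' zero-sum kernel) are selected and connected components are extracted
#' with the same connectivity used for detection. Each component becomes an
#' individual detection inheriting the demographic class of its parent:
#' every polygon derived from an adult aggregation is assumed to be an
#' adult, and every polygon from a YOY aggregation a YOY. If no cell
#' responds, the whole aggregation is returned as a single individual
#' (a warm object above threshold is at least one animal).
#'
#' Split polygons are re-measured (area, mean temperature, solidity) but
#' not re-classified.
#'
#' @param aggregation One-row detection tibble labelled `yoy_aggregation`
#'   or `adult_aggregation`.
#' @param raster The source [thermal_raster()] (raw temperatures; the
#'   filter needs the continuous values, not the binary grid).
#' @param params A [classification_params()] (supplies connectivity).
#' @param kernel A [high_pass_kernel()].
#' @param response_min Post-filter selection threshold (strict `>`).
#' @param next_id First id to assign to split outputs.
#' @return A detection tibble of individuals with `parent_id` set.
#' @export
split_aggregation <- function(aggregation, raster,
                              params = classification_params(),
                              kernel = high_pass_kernel(),
                              response_min = 0, next_id = NULL) {
  stopifnot(nrow(aggregation) == 1L)
  lab <- aggregation$label
  if (!lab %in% c("yoy_aggregation", "adult_aggregation"))
    stop("split_aggregation() expects an aggregation polygon, got label '",
         lab, "'", call. = FALSE)
  child_label <- if (lab == "adult_aggregation") "individual_adult"
                 else "individual_yoy"
  cells <- aggregation$cells[[1]] %||% polygon_cells(aggregation$geometry[[1]],
                                                     raster)
  if (is.null(next_id)) next_id <- aggregation$id + 1L

  # filter on a bounding window (with margin) of raw temperatures
  win <- crop_window(raster, cells, margin = 2L)
  resp <- high_pass(win$raster, kernel)
  sel <- matrix(FALSE, nrow(win$raster$values), ncol(win$raster$values))
  loc <- cbind(cells[, 1] - win$row0, cells[, 2] - win$col0)
  sel[loc] <- resp[loc] > response_min
  comps <- extract_clusters(sel, params$connectivity)
  if (length(comps) == 0L) {
    out <- polygonize_cluster(cells, raster, id = next_id)
  } else {
    out <- dplyr::bind_rows(purrr::imap(comps, function(cl, i) {
      glob <- cbind(row = cl[, 1] + win$row0, col = cl[, 2] + win$col0)
      polygonize_cluster(glob, raster, id = next_id + i - 1L)
    }))
  }
  out$label <- child_label
  out$parent_id <- aggregation$id
  out
}

#' Split every aggregation in a detection set
#'
#' Applies [split_aggregation()] to each polygon labelled as an
#' aggregation and returns the detection tibble with those rows replaced by
#' their individual children (ids continue after the existing maximum).
#' Individuals and unclassified polygons pass through unchanged.
#'
#' @inheritParams split_aggregation
#' @param detections A classified detection tibble.
#' @return A detection tibble containing no aggregation labels.
#' @export
split_aggregations <- function(detections, raster,
                               params = classification_params(),
                               kernel = high_pass_kernel(),
                               response_min = 0) {
  is_agg <- detections$label %in% c("yoy_aggregation", "adult_aggregation")
  if (!any(is_agg)) return(detections)
  next_id <- max(detections$id) + 1L
  kept <- detections[!is_agg, , drop = FALSE]
  children <- list()
  for (i in which(is_agg)) {
    ch <- split_aggregation(detections[i, , drop = FALSE], raster,
                            params = params, kernel = kernel,
                            response_min = response_min, next_id = next_id)
    next_id <- next_id + nrow(ch)
    children[[length(children) + 1L]] <- ch
  }
  dplyr::bind_rows(kept, children)
}

# window of a raster covering `cells` plus a margin; returns the cropped
# thermal_raster and the (row, col) offsets of the crop
crop_window <- function(raster, cells, margin = 2L) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  r1 <- max(1L, min(cells[, 1]) - margin); r2 <- min(nr, max(cells[, 1]) + margin)
  c1 <- max(1L, min(cells[, 2]) - margin); c2 <- min(nc, max(cells[, 2]) + margin)
  vals <- raster$values[r1:r2, c1:c2, drop = FALSE]
  sub <- thermal_raster(vals,
                        xmin = raster$xmin + (c1 - 1L) * raster$gsd_m,
                        ymax = raster$ymax - (r1 - 1L) * raster$gsd_m,
                        gsd_m = raster$gsd_m, crs = raster$crs,
                        nodata = raster$nodata)
  list(raster = sub, row0 = r1 - 1L, col0 = c1 - 1L)
}

# recover a polygon's member cells from its rings (pixel-centre test);
# used when detections were round-tripped through GeoJSON and the cells
# column was lost
polygon_cells <- function(rings, raster) {
  bb <- rings_bbox(rings)
  g <- raster$gsd_m
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cmin <- max(1L, floor((bb["xmin"] - raster$xmin) / g) + 1L)
  cmax <- min(nc, ceiling((bb["xmax"] - raster$xmin) / g))
  rmin <- max(1L, floor((raster$ymax - bb["ymax"]) / g) + 1L)
  rmax <- min(nr, ceiling((raster$ymax - bb["ymin"]) / g))
  cols <- rep(cmin:cmax, each = rmax - rmin + 1L)
  rows <- rep(rmin:rmax, times = cmax - cmin + 1L)
  xy <- cell_center_xy(raster, rows, cols)
  hit <- points_in_rings(xy[, 1], xy[, 2], rings)
  cbind(row = rows[hit], col = cols[hit])
}
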