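# GeoJSON (RFC 7946) reading/writing via jsonlite, for exclusion masks,
# detection polygons and annotation points. Geometries use the package's
# ring-list representation (see geometry.R).

geojson_polygon_coords <- function(rings) {
  lapply(rings, function(ring) {
    closed <- rbind(ring, ring[1, , drop = FALSE])
    lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
  })
}

parse_polygon_coords <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
}

read_geojson <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Read an exclusion mask
#'
#' Reads polygons (GeoJSON `Polygon`/`MultiPolygon` features) delimiting
#' areas to remove from analysis — typically landscape whose ambient
#' temperature overlaps seal body temperature.
#'
#' @param path Path to a GeoJSON file.
#' @param crs CRS the mask coordinates are in (defaults to unknown; set it
#'   to enable the raster/mask CRS check).
#' @return An `exclusion_mask`: list of polygons, each a list of rings.
#' @export
read_mask <- function(path, crs = NULL) {
  gj <- read_geojson(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      polys[[length(polys) + 1L]] <- parse_polygon_coords(geom$coordinates)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (p in geom$coordinates)
        polys[[length(polys) + 1L]] <- parse_polygon_coords(p)
    } else {
      stop("mask features must be Polygon or MultiPolygon, got ",
           geom$type, call. = FALSE)
    }
  }
  exclusion_mask(polys, crs = crs)
}

#' Build an exclusion mask from polygons
#'
#' @param polygons List of polygons; each polygon is a list of rings, each
#'   ring an n x 2 matrix of world coordinates (exterior first). A single
#'   matrix is also accepted as a one-ring polygon.
#' @param crs Optional CRS identifier of the polygon coordinates.
#' @return An object of class `exclusion_mask`.
#' @export
exclusion_mask <- function(polygons = list(), crs = NULL) {
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  structure(list(polygons = polygons, crs = crs), class = "exclusion_mask")
}

#' Mask out excluded areas of a thermal raster
#'
#' Sets to nodata every pixel whose centre falls inside (or on the boundary
#' of) any mask polygon; all other cells are untouched. Masking is
#' idempotent.
#'
#' @param raster A [thermal_raster()].
#' @param mask An [exclusion_mask()] in the same CRS.
#' @return The masked [thermal_raster()].
#' @export
apply_exclusion_mask <- function(raster, mask) {
  stopifnot(inherits(raster, "thermal_raster"), inherits(mask, "exclusion_mask"))
  if (!is.null(mask$crs) && !identical(trimws(mask$crs), trimws(raster$crs)))
    stop("mask CRS (", mask$crs, ") does not match raster CRS (",
         raster$crs, ")", call. = FALSE)
  if (length(mask$polygons) == 0L) return(raster)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v); g <- raster$gsd_m
  for (poly in mask$polygons) {
    bb <- rings_bbox(poly)
    # candidate cells: centres within the polygon bbox
    cmin <- max(1L, floor((bb["xmin"] - raster$xmin) / g + 0.5) + 1L)
    cmax <- min(nc, ceiling((bb["xmax"] - raster$xmin) / g + 0.5))
    rmin <- max(1L, floor((raster$ymax - bb["ymax"]) / g + 0.5) + 1L)
    rmax <- min(nr, ceiling((raster$ymax - bb["ymin"]) / g + 0.5))
    if (cmin > cmax || rmin > rmax) next
    cols <- rep(cmin:cmax, each = rmax - rmin + 1L)
    rows <- rep(rmin:rmax, times = cmax - cmin + 1L)
    xy <- cell_center_xy(raster, rows, cols)
    hit <- points_in_rings(xy[, 1], xy[, 2], poly)
    v[cbind(rows[hit], cols[hit])] <- NA_real_
  }
  raster$values <- v
  raster
}

#' Write detections to GeoJSON
#'
#' Serialises a detection tibble as an RFC 7946 FeatureCollection with
#' per-feature attributes `id`, `class`, `area_m2`, `mean_temp_c`,
#' `chull_ratio`, `pixel_count` and `parent_id`.
#'
#' @param detections A detection tibble (see [detect_seals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  feats <- purrr::pmap(
    list(detections$id, detections$label, detections$area_m2,
         detections$mean_temp_c, detections$chull_ratio,
         detections$pixel_count, detections$parent_id, detections$geometry),
    function(id, label, area, temp, ratio, npx, parent, rings) {
      list(type = "Feature",
           properties = list(
             id = id, class = label, area_m2 = area, mean_temp_c = temp,
             chull_ratio = ratio, pixel_count = npx,
             parent_id = if (is.na(parent)) NULL else parent),
           geometry = list(type = "Polygon",
                           coordinates = geojson_polygon_coords(rings)))
    })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read detections from GeoJSON
#'
#' Inverse of [write_detections()]. The pixel-cluster membership
#' (`cells` column) is not stored on disk; operations that need it
#' (aggregation splitting) recover it from the polygon and the raster.
#'
#' @param path Path to a GeoJSON FeatureCollection written by
#'   [write_detections()].
#' @return A detection tibble.
#' @export
read_detections <- function(path) {
  gj <- read_geojson(path)
  feats <- gj$features %||% list()
  rows <- purrr::map(feats, function(f) {
    p <- f$properties
    tibble::tibble(
      id = as.integer(p$id),
      pixel_count = as.integer(p$pixel_count),
      area_m2 = as.numeric(p$area_m2),
      mean_temp_c = as.numeric(p$mean_temp_c),
      chull_ratio = as.numeric(p$chull_ratio),
      label = as.character(p$class %||% NA_character_),
      parent_id = as.integer(p$parent_id %||% NA_integer_),
      geometry = list(parse_polygon_coords(f$geometry$coordinates)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty_detections() else out
}

#' Read annotation points
#'
#' Reads human-placed, class-labelled seal annotation points ("ITag
#' points") from CSV (columns `id`, `x`, `y`, `label`) or GeoJSON Point
#' features (property `label` or `class`). Labels must be `"adult"` or
#' `"yoy"`.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @return A tibble with columns `id`, `x`, `y`, `label`.
#' @export
read_points <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    pts <- tibble::tibble(id = as.integer(df$id), x = as.numeric(df$x),
                          y = as.numeric(df$y), label = as.character(df$label))
  } else {
    gj <- read_geojson(path)
    feats <- gj$features %||% list()
    pts <- dplyr::bind_rows(purrr::map(feats, function(f) {
      p <- f$properties
      tibble::tibble(id = as.integer(p$id),
                     x = as.numeric(f$geometry$coordinates[[1]]),
                     y = as.numeric(f$geometry$coordinates[[2]]),
                     label = as.character((p$label %||% p$class) %||% NA_character_))
    }))
    if (nrow(pts) == 0L)
      pts <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                            label = character())
  }
  validate_points(pts)
  pts
}

validate_points <- function(pts) {
  if (nrow(pts) == 0L) return(invisible(TRUE))
  bad <- setdiff(unique(pts$label), c("adult", "yoy"))
  if (length(bad) > 0L)
    stop("point labels must be 'adult' or 'yoy'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(pts$x)) || any(!is.finite(pts$y)))
    stop("point coordinates must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Write annotation points
#'
#' @param points Tibble with columns `id`, `x`, `y`, `label`.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.geojson`).
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(points[, c("id", "x", "y", "label")], path,
                     row.names = FALSE)
  } else {
    feats <- purrr::pmap(points[, c("id", "x", "y", "label")],
      function(id, x, y, label) {
        list(type = "Feature",
             properties = list(id = id, label = label),
             geometry = list(type = "Point", coordinates = c(x, y)))
      })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
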