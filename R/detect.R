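# Detection core: thresholding, connected-component clustering, polygon
# attributes. This is the front half of the census pipeline: warm pixels
# are selected with an inclusive temperature cut, grouped into connected
# clusters, and each cluster becomes an attributed polygon (area, mean
# temperature, convex-hull solidity) for rule-based classification.

#' Select pixels at or above a temperature threshold
#'
#' A cell is selected iff it is not nodata and its temperature is greater
#' than or equal to `t_min` (the cut is inclusive). The survey workflow
#' picks `t_min` per site, after brief visual inspection, as the lowest
#' temperature that separates seals from the warmest landscape (9 degC at
#' the training colony, 5.5 degC at the colder prediction colony).
#'
#' @param raster A [thermal_raster()].
#' @param t_min Detection threshold in degrees C (inclusive).
#' @return A logical matrix of the raster's shape; nodata cells are `FALSE`.
#' @export
select_hot_pixels <- function(raster, t_min) {
  stopifnot(inherits(raster, "thermal_raster"), is.finite(t_min))
  sel <- !is.na(raster$values) & raster$values >= t_min
  sel
}

#' Extract connected clusters of selected pixels
#'
#' Groups `TRUE` cells of a binary grid into maximal connected components.
#' The default rook (4-neighbour) connectivity matches GIS raster-to-polygon
#' conversion, where diagonal-only neighbours become separate polygons;
#' queen (8-neighbour) connectivity is available for comparison.
#'
#' @param binary Logical matrix (e.g. from [select_hot_pixels()]).
#' @param connectivity 4 or 8.
#' @return A list of clusters, each an integer matrix with columns
#'   `row`, `col`. Clusters are ordered by their first cell in column-major
#'   scan order, and together partition the selected cells.
#' @export
extract_clusters <- function(binary, connectivity = 4) {
  stopifnot(is.matrix(binary), is.logical(binary))
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(binary); nc <- ncol(binary)
  idx <- which(binary)  # column-major order
  if (length(idx) == 0L) return(list())
  lab <- integer(nr * nc)
  # neighbour offsets in flat (column-major) indexing, with row guards
  out <- vector("list", 64L)
  n_clusters <- 0L
  stack <- integer(length(idx))
  for (seed in idx) {
    if (lab[seed] != 0L) next
    n_clusters <- n_clusters + 1L
    lab[seed] <- n_clusters
    stack[1L] <- seed
    top <- 1L
    members <- integer(0)
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      members <- c(members, cur)
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      nbr <- integer(0)
      if (r > 1L) nbr <- c(nbr, cur - 1L)
      if (r < nr) nbr <- c(nbr, cur + 1L)
      if (cc > 1L) nbr <- c(nbr, cur - nr)
      if (cc < nc) nbr <- c(nbr, cur + nr)
      if (connectivity == 8) {
        if (r > 1L && cc > 1L) nbr <- c(nbr, cur - nr - 1L)
        if (r < nr && cc > 1L) nbr <- c(nbr, cur - nr + 1L)
        if (r > 1L && cc < nc) nbr <- c(nbr, cur + nr - 1L)
        if (r < nr && cc < nc) nbr <- c(nbr, cur + nr + 1L)
      }
      nbr <- nbr[binary[nbr] & lab[nbr] == 0L]
      if (length(nbr) > 0L) {
        lab[nbr] <- n_clusters
        stack[(top + 1L):(top + length(nbr))] <- nbr
        top <- top + length(nbr)
      }
    }
    r <- ((members - 1L) %% nr) + 1L
    cc <- ((members - 1L) %/% nr) + 1L
    if (n_clusters > length(out)) out <- c(out, vector("list", length(out)))
    out[[n_clusters]] <- cbind(row = r, col = cc)
  }
  out[seq_len(n_clusters)]
}

#' Convert a pixel cluster into an attributed seal polygon
#'
#' Builds the world-coordinate polygon covering the cluster's pixel squares
#' and records the attributes the classifier uses: planar area
#' (`pixel_count * gsd^2`, exact for unsimplified rasterised outlines),
#' arithmetic mean member temperature, and convex-hull solidity.
#'
#' @param cells Integer matrix with columns `row`, `col`.
#' @param raster The source [thermal_raster()].
#' @param id Integer id to assign.
#' @return A one-row detection tibble (see [detect_seals()]).
#' @export
polygonize_cluster <- function(cells, raster, id = 1L) {
  stopifnot(nrow(cells) >= 1L)
  rings <- trace_cluster_rings(cells, raster)
  npx <- nrow(cells)
  area <- npx * raster$gsd_m^2
  tibble::tibble(
    id = as.integer(id),
    pixel_count = npx,
    area_m2 = area,
    mean_temp_c = mean(raster$values[cells]),
    chull_ratio = convex_hull_ratio(rings),
    label = NA_character_,
    parent_id = NA_integer_,
    geometry = list(rings),
    cells = list(cells))
}

empty_detections <- function() {
  tibble::tibble(
    id = integer(), pixel_count = integer(), area_m2 = numeric(),
    mean_temp_c = numeric(), chull_ratio = numeric(), label = character(),
    parent_id = integer(), geometry = list(), cells = list())
}

#' Detect warm objects in a thermal raster
#'
#' Runs thresholding, clustering and polygonisation in one step. One-pixel
#' clusters are kept: at 8 cm GSD a single warm pixel can be a real
#' young-of-the-year seal, so no winnowing filter is applied.
#'
#' @param raster A [thermal_raster()].
#' @param t_min Detection threshold in degrees C (inclusive).
#' @param connectivity Clustering connectivity, 4 (default) or 8.
#' @return A detection tibble with one row per warm polygon and columns
#'   `id`, `pixel_count`, `area_m2`, `mean_temp_c`, `chull_ratio`, `label`
#'   (unset), `parent_id` (unset), `geometry` (list of ring lists) and
#'   `cells` (list of row/col matrices).
#' @examples
#' r <- thermal_raster(matrix(c(2, 2, 12, 2), 2, 2), 0, 10, 0.08, "EPSG:32620")
#' detect_seals(r, t_min = 9)
#' @export
detect_seals <- function(raster, t_min, connectivity = 4) {
  sel <- select_hot_pixels(raster, t_min)
  clusters <- extract_clusters(sel, connectivity)
  if (length(clusters) == 0L) return(empty_detections())
  dplyr::bind_rows(purrr::imap(clusters, function(cl, i)
    polygonize_cluster(cl, raster, id = i)))
}
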