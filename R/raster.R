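#' Thermal raster objects
#'
#' A `thermal_raster` is a single-band grid of surface temperatures in
#' degrees Celsius with a simple north-up affine georeference: the map
#' coordinate of the grid origin (upper-left corner), a square pixel size
#' (the ground sampling distance, GSD) in metres, and a projected CRS.
#' Row 1 is the northernmost row; the centre of pixel `(r, c)` sits at
#' `(xmin + (c - 0.5) * gsd, ymax - (r - 0.5) * gsd)`.
#'
#' @param values Numeric matrix of temperatures (degrees C). `NA` marks
#'   nodata cells.
#' @param xmin,ymax World coordinates (m) of the upper-left corner of the
#'   upper-left pixel.
#' @param gsd_m Pixel edge length in metres (must be > 0).
#' @param crs Coordinate reference system identifier: an `"EPSG:<code>"`
#'   string or WKT. Must be a projected, metre-unit CRS.
#' @param nodata Sentinel value used on disk for nodata (stored as `NA`
#'   in memory).
#'
#' @return An object of class `thermal_raster`: a list with elements
#'   `values`, `xmin`, `ymax`, `gsd_m`, `crs`, `nodata`.
#' @examples
#' r <- thermal_raster(matrix(c(8, 10, 12, NA), 2, 2), xmin = 0, ymax = 10,
#'                     gsd_m = 0.08, crs = "EPSG:32620")
#' dim(r$values)
#' @export
thermal_raster <- function(values, xmin, ymax, gsd_m, crs, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  if (!is.numeric(gsd_m) || length(gsd_m) != 1L || !is.finite(gsd_m) || gsd_m <= 0)
    stop("`gsd_m` must be a single positive number (metres)", call. = FALSE)
  check_projected_crs(crs)
  storage.mode(values) <- "double"
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(is.infinite(values) | is.nan(values)))
    stop("all non-nodata temperatures must be finite", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         gsd_m = as.numeric(gsd_m), crs = crs, nodata = as.numeric(nodata)),
    class = "thermal_raster")
}

#' @export
print.thermal_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<thermal_raster> %d x %d cells, gsd %.3g m, crs %s\n",
              nrow(v), ncol(v), x$gsd_m, crs_label(x$crs)))
  cat(sprintf("  extent x [%.2f, %.2f]  y [%.2f, %.2f] m\n",
              x$xmin, x$xmin + ncol(v) * x$gsd_m,
              x$ymax - nrow(v) * x$gsd_m, x$ymax))
  if (all(is.na(v))) {
    cat(sprintf("  all %d cells nodata\n", length(v)))
  } else {
    cat(sprintf("  temps [%.2f, %.2f] degC, %d nodata cells\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  }
  invisible(x)
}

crs_label <- function(crs) {
  if (grepl("^EPSG:", crs, ignore.case = TRUE)) crs else "WKT"
}

# Common geographic (degree-unit) EPSG codes. WKT with a geographic root is
# also rejected: classifier thresholds are in m^2, so only projected,
# metre-unit systems are meaningful.
.geographic_epsg <- c(4326L, 4269L, 4267L, 4258L, 4617L, 4283L, 4148L)

check_projected_crs <- function(crs) {
  if (is.null(crs) || length(crs) != 1L || is.na(crs) || !nzchar(trimws(crs)))
    stop("raster has no CRS; supply a projected, metre-unit CRS ",
         "(e.g. \"EPSG:32620\")", call. = FALSE)
  crs <- trimws(crs)
  if (grepl("^EPSG:\\s*[0-9]+$", crs, ignore.case = TRUE)) {
    code <- as.integer(sub("(?i)^EPSG:\\s*", "", crs, perl = TRUE))
    if (code %in% .geographic_epsg)
      stop("CRS EPSG:", code, " is geographic (degree units); ",
           "reproject the raster to a projected, metre-unit CRS", call. = FALSE)
    return(invisible(TRUE))
  }
  if (grepl("^(GEOGCS|GEOGCRS)", crs, ignore.case = TRUE))
    stop("geographic (degree-unit) CRS; reproject the raster to a ",
         "projected, metre-unit CRS", call. = FALSE)
  if (grepl("^(PROJCS|PROJCRS)", crs, ignore.case = TRUE)) {
    if (grepl("UNIT\\s*\\[\\s*\"(degree|Degree)", crs))
      stop("CRS linear unit is not metres; reproject", call. = FALSE)
    if (grepl("UNIT\\s*\\[", crs) &&
        !grepl("UNIT\\s*\\[\\s*\"[Mm]et(re|er)s?\"", crs))
      stop("CRS linear unit is not metres; reproject", call. = FALSE)
    return(invisible(TRUE))
  }
  # unrecognised identifier: accept, trusting the caller
  invisible(TRUE)
}

#' Pixel centre coordinates
#'
#' World coordinates of every pixel centre, as a tibble in row-major order.
#' Mostly an internal helper, exported because it defines the package's
#' raster/world convention in one place.
#'
#' @param raster A [thermal_raster()].
#' @return A tibble with columns `row`, `col`, `x`, `y`, `temp_c`.
#' @export
pixel_centers <- function(raster) {
  stopifnot(inherits(raster, "thermal_raster"))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  g <- raster$gsd_m
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = raster$xmin + (rep(seq_len(nc), each = nr) - 0.5) * g,
    y = raster$ymax - (rep(seq_len(nr), times = nc) - 0.5) * g,
    temp_c = as.vector(raster$values))
}

# world coordinates of a set of (row, col) cell centres
cell_center_xy <- function(raster, rows, cols) {
  cbind(x = raster$xmin + (cols - 0.5) * raster$gsd_m,
        y = raster$ymax - (rows - 0.5) * raster$gsd_m)
}

#' Read a georeferenced thermal index raster
#'
#' Reads a single-band temperature raster (degrees C). Two containers are
#' supported:
#'
#' * **ESRI ASCII grid** (`.asc`): the plain-text ArcGIS interchange grid.
#'   The `NODATA_value` header is honoured; the CRS is read from a `.prj`
#'   sidecar (WKT) unless given via `crs`.
#' * **GeoTIFF** (`.tif`/`.tiff`), read-only: pixel values are read with
#'   the `tiff` package; because geokeys embedded in the TIFF are not
#'   accessible here, the georeference must come from an ESRI world file
#'   (`.tfw`) and the CRS from a `.prj` sidecar or the `crs` argument.
#'
#' @param path Path to the raster file.
#' @param crs Optional CRS override (otherwise the `.prj` sidecar is used).
#' @param nodata Optional nodata override for TIFF input (ASCII grids carry
#'   their own `NODATA_value`).
#' @return A [thermal_raster()].
#' @export
read_thermal_index <- function(path, crs = NULL, nodata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    read_asc_grid(path, crs = crs)
  } else if (ext %in% c("tif", "tiff")) {
    read_tif_grid(path, crs = crs, nodata = nodata)
  } else {
    stop("unsupported raster format '.", ext, "'; expected .asc or .tif",
         call. = FALSE)
  }
}

sidecar_path <- function(path, ext) {
  paste0(tools::file_path_sans_ext(path), ".", ext)
}

read_prj_sidecar <- function(path) {
  prj <- sidecar_path(path, "prj")
  if (!file.exists(prj)) return(NULL)
  paste(readLines(prj, warn = FALSE), collapse = "")
}

read_asc_grid <- function(path, crs = NULL) {
  lines <- readLines(path, n = 6L, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  if (is.null(xll) || is.null(yll))
    stop("ASCII grid header lacks xllcorner/yllcorner", call. = FALSE)
  crs <- crs %||% read_prj_sidecar(path)
  if (is.null(crs))
    stop("no CRS for ", path, ": add a .prj sidecar or pass `crs`",
         call. = FALSE)
  nodata <- hdr$nodata_value %||% -9999
  thermal_raster(m, xmin = xll, ymax = yll + nr * hdr$cellsize,
                 gsd_m = hdr$cellsize, crs = crs, nodata = nodata)
}

read_tif_grid <- function(path, crs = NULL, nodata = NULL) {
  img <- tiff::readTIFF(path, all = FALSE, info = TRUE)
  if (is.array(img) && length(dim(img)) == 3L)
    stop("expected single band, got ", dim(img)[3], "-band raster", call. = FALSE)
  if (!is.matrix(img)) stop("could not read ", path, " as a 2-D grid", call. = FALSE)
  tfw <- sidecar_path(path, "tfw")
  if (!file.exists(tfw))
    stop("GeoTIFF geokeys are not readable here; provide an ESRI world ",
         "file (", basename(tfw), ")", call. = FALSE)
  w <- scan(tfw, what = double(), quiet = TRUE)
  if (length(w) != 6L) stop("malformed world file ", tfw, call. = FALSE)
  # A B D E C F: x-scale, rotations, y-scale (negative), centre of UL pixel
  if (abs(w[2]) > 1e-12 || abs(w[3]) > 1e-12)
    stop("rotated rasters are not supported", call. = FALSE)
  if (abs(w[1] + w[4]) > 1e-9 * abs(w[1]))
    stop("non-square pixels are not supported", call. = FALSE)
  g <- w[1]
  crs <- crs %||% read_prj_sidecar(path)
  if (is.null(crs))
    stop("no CRS for ", path, ": add a .prj sidecar or pass `crs`",
         call. = FALSE)
  m <- matrix(as.numeric(img), nrow(img), ncol(img))  # drop TIFF tag attrs
  thermal_raster(m, xmin = w[5] - g / 2, ymax = w[6] + g / 2, gsd_m = g,
                 crs = crs, nodata = nodata %||% -9999)
}

#' Write a thermal raster as an ESRI ASCII grid
#'
#' Writes the grid as a plain-text `.asc` file (with `NODATA_value`) plus a
#' `.prj` sidecar carrying the CRS, readable by ArcGIS/QGIS/GDAL and by
#' [read_thermal_index()].
#'
#' @param raster A [thermal_raster()].
#' @param path Output path (`.asc`).
#' @param digits Significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_thermal_index <- function(raster, path, digits = 7) {
  stopifnot(inherits(raster, "thermal_raster"))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", raster$xmin),
    sprintf("yllcorner %.10g", raster$ymax - nr * raster$gsd_m),
    sprintf("cellsize %.10g", raster$gsd_m),
    sprintf("NODATA_value %.10g", raster$nodata)), con)
  v[is.na(v)] <- raster$nodata
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(body, con)
  writeLines(raster$crs, sidecar_path(path, "prj"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
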