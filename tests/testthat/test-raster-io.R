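test_that("ASCII grid write/read round-trips values, georeference and nodata", {
  set.seed(1)
  m <- matrix(round(runif(120, -5, 25), 3), 10, 12)
  m[c(3, 17, 40, 77)] <- NA
  r <- tr(m, gsd = 0.08, xmin = 500000, ymax = 5100000)
  path <- file.path(tempdir(), "grid.asc")
  write_thermal_index(r, path)
  r2 <- read_thermal_index(path)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_identical(sum(is.na(r2$values)), 4L)
  expect_equal(r2$gsd_m, 0.08)
  expect_equal(r2$xmin, 500000)
  expect_equal(r2$ymax, 5100000)
  expect_identical(r2$crs, CRS_UTM)
})

test_that("raster constructor enforces its invariants", {
  m <- matrix(1, 2, 2)
  expect_error(thermal_raster(m, 0, 1, -0.1, CRS_UTM), "positive")
  expect_error(thermal_raster(m, 0, 1, 0.08, NA), "CRS")
  expect_error(thermal_raster(m, 0, 1, 0.08, "EPSG:4326"), "geographic")
  expect_error(thermal_raster(m, 0, 1, 0.08,
                              'GEOGCS["WGS 84",UNIT["degree",0.01]]'),
               "reproject")
  expect_error(thermal_raster(matrix(Inf, 1, 1), 0, 1, 0.08, CRS_UTM),
               "finite")
  # nodata sentinel becomes NA
  r <- thermal_raster(matrix(c(1, -9999, 3, 4), 2, 2), 0, 1, 0.08, CRS_UTM)
  expect_identical(sum(is.na(r$values)), 1L)
})

test_that("single-band float GeoTIFF reads via world file and prj sidecar", {
  base <- file.path(tempdir(), "thermal")
  vals <- matrix(runif(50), 5, 10)  # tiff floats must sit in [0, 1]
  tiff::writeTIFF(vals, paste0(base, ".tif"), bits.per.sample = 32L)
  # world file: x-scale, 0, 0, -y-scale, centre-x, centre-y of UL pixel
  writeLines(c("0.08", "0", "0", "-0.08", "100.04", "499.96"),
             paste0(base, ".tfw"))
  writeLines(CRS_UTM, paste0(base, ".prj"))
  r <- read_thermal_index(paste0(base, ".tif"))
  expect_equal(r$values, vals, tolerance = 1e-6)
  expect_equal(r$gsd_m, 0.08)
  expect_equal(r$xmin, 100)
  expect_equal(r$ymax, 500)

  # multi-band input is refused with the band count in the message
  rgb <- array(runif(60), dim = c(5, 4, 3))
  tiff::writeTIFF(rgb, paste0(base, "_rgb.tif"), bits.per.sample = 32L)
  writeLines(c("0.08", "0", "0", "-0.08", "0.04", "0.04"),
             paste0(base, "_rgb.tfw"))
  expect_error(read_thermal_index(paste0(base, "_rgb.tif"), crs = CRS_UTM),
               "single band")

  # no .prj and no crs argument: error
  file.remove(paste0(base, ".prj"))
  expect_error(read_thermal_index(paste0(base, ".tif")), "CRS")
  expect_error(read_thermal_index(file.path(tempdir(), "nope.asc")),
               "not found")
})

test_that("exclusion masking uses pixel centres, is idempotent and local", {
  set.seed(2)
  m <- matrix(runif(400, 0, 20), 20, 20)
  r <- tr(m, gsd = 0.1, xmin = 0, ymax = 2)  # centres at 0.05, 0.15, ...
  expect_identical(apply_exclusion_mask(r, exclusion_mask())$values, r$values)

  # axis-aligned rectangle covering exactly centres in x {0.05..0.35},
  # y {0.05, 0.15, 0.25}: 4 columns x 3 rows = 12 pixels (rows 18-20)
  rect <- cbind(x = c(0, 0.4, 0.4, 0), y = c(0, 0, 0.3, 0.3))
  mk <- exclusion_mask(list(rect), crs = CRS_UTM)
  masked <- apply_exclusion_mask(r, mk)
  expect_identical(sum(is.na(masked$values)), 12L)
  # only the expected block is gone; everything else bitwise identical
  expect_true(all(is.na(masked$values[18:20, 1:4])))
  keep <- !is.na(masked$values)
  expect_identical(masked$values[keep], r$values[keep])
  # idempotent
  expect_identical(apply_exclusion_mask(masked, mk)$values, masked$values)

  # full-extent mask removes everything
  all_rect <- cbind(x = c(-1, 3, 3, -1), y = c(-1, -1, 3, 3))
  expect_true(all(is.na(apply_exclusion_mask(r,
    exclusion_mask(list(all_rect)))$values)))

  expect_error(apply_exclusion_mask(r, exclusion_mask(list(rect),
                                                      crs = "EPSG:32619")),
               "CRS")
})

test_that("masks read from GeoJSON behave like in-memory masks", {
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = NULL,
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0, 0), list(0.4, 0), list(0.4, 0.3), list(0, 0.3), list(0, 0)))))))
  p <- file.path(tempdir(), "mask.geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
  mk <- read_mask(p)
  expect_length(mk$polygons, 1)
  expect_equal(nrow(mk$polygons[[1]][[1]]), 4)  # closing vertex dropped
})
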