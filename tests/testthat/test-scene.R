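test_that("identical config and seed give bit-identical scenes", {
  cfg <- small_colony_config(5, 3, seed = 77)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(a$truth, b$truth)
  # and the global RNG state is left alone
  set.seed(1); before <- runif(1)
  generate_scene(cfg)
  set.seed(1)
  expect_identical(runif(1), before)
})

test_that("an empty scene is pure background below any 6-sigma excursion", {
  cfg <- scene_config(extent_m = c(15, 15),
                      warm_patches = list(count = 0, radius_m = c(0.4, 1.2),
                                          excess_c = c(3, 6)),
                      yoy = list(count = 0, body_temp_c = c(12, 14),
                                 area_m2 = c(0.25, 0.60), aspect = c(1.6, 2.6)),
                      adult = list(count = 0, body_temp_c = c(13, 16),
                                   area_m2 = c(1.2, 3.0), aspect = c(1.8, 2.8)),
                      seed = 5)
  sc <- generate_scene(cfg)
  expect_identical(nrow(sc$truth$points), 0L)
  expect_lt(max(sc$raster$values), 2 + 6 * 0.6)
  expect_identical(nrow(detect_seals(sc$raster, 9)), 0L)
})

test_that("truth is conserved and every point sits in its seal's footprint", {
  sc <- generate_scene(small_colony_config(8, 4, seed = 21))
  expect_identical(nrow(sc$truth$points), 12L)
  expect_identical(nrow(sc$truth$seals), 12L)
  det <- detect_seals(sc$raster, 9)
  expect_identical(nrow(det), 12L)
  hits <- vapply(seq_len(nrow(sc$truth$points)), function(i) {
    any(vapply(det$geometry, function(rings)
      sealtherm:::points_in_rings(sc$truth$points$x[i], sc$truth$points$y[i],
                                  rings), TRUE))
  }, TRUE)
  expect_true(all(hits))
})

test_that("a configured footprint area is recovered by detection", {
  cfg <- scene_config(extent_m = c(12, 12),
                      warm_patches = list(count = 0, radius_m = c(0.4, 1.2),
                                          excess_c = c(3, 6)),
                      yoy = list(count = 0, body_temp_c = c(12, 14),
                                 area_m2 = c(0.25, 0.60), aspect = c(1.6, 2.6)),
                      adult = list(count = 1, body_temp_c = c(14, 14),
                                   area_m2 = c(1.6, 1.6), aspect = c(2, 2)),
                      seed = 9)
  sc <- generate_scene(cfg)
  d <- detect_seals(sc$raster, 9)
  expect_identical(nrow(d), 1L)
  expect_gte(d$area_m2, 1.4)
  expect_lte(d$area_m2, 1.8)
})

test_that("seals colder than the ambient band disappear from detection", {
  cfg <- scene_config(extent_m = c(15, 15),
                      warm_patches = list(count = 0, radius_m = c(0.4, 1.2),
                                          excess_c = c(3, 6)),
                      yoy = list(count = 5, body_temp_c = c(0, 1),
                                 area_m2 = c(0.25, 0.60), aspect = c(1.6, 2.6)),
                      adult = list(count = 3, body_temp_c = c(0.5, 1.5),
                                   area_m2 = c(1.2, 3.0), aspect = c(1.8, 2.8)),
                      seed = 33)
  sc <- generate_scene(cfg)
  expect_identical(nrow(detect_seals(sc$raster, 9)), 0L)
})

test_that("warm landscape patches stay below the detection threshold", {
  cfg <- scene_config(extent_m = c(20, 20),
                      warm_patches = list(count = 8, radius_m = c(0.4, 1.2),
                                          excess_c = c(3, 6)),
                      yoy = list(count = 0, body_temp_c = c(12, 14),
                                 area_m2 = c(0.25, 0.60), aspect = c(1.6, 2.6)),
                      adult = list(count = 0, body_temp_c = c(13, 16),
                                   area_m2 = c(1.2, 3.0), aspect = c(1.8, 2.8)),
                      seed = 3)
  sc <- generate_scene(cfg)
  expect_gt(max(sc$raster$values), 2 + 6 * 0.6)  # patches are really there
  expect_identical(nrow(detect_seals(sc$raster, 9)), 0L)
})

test_that("overcrowded configurations fail loudly", {
  cfg <- small_colony_config(80, 0, seed = 2, extent = c(6, 6))
  expect_error(generate_scene(cfg), "dense")
})

test_that("written truth feeds the assessment without adapters", {
  sc <- generate_scene(small_colony_config(6, 3, seed = 55))
  p <- file.path(tempdir(), "truth.csv")
  write_truth(sc$truth, p)
  pts <- read_points(p)
  expect_identical(nrow(pts), 9L)
  cen <- run_pipeline(sc$raster, classification_params(mode = "simplified"))
  tab <- accuracy_assessment(snap_points(pts, cen$detections), cen$detections)
  expect_identical(sum(tab$n[tab$category == "true_positive"]), 9L)
  expect_identical(sum(tab$n[tab$category == "missed_by_model"]), 0L)
})

test_that("scene configs validate their class area bands", {
  expect_error(scene_config(yoy = list(count = 1, body_temp_c = c(12, 14),
                                       area_m2 = c(0.5, 0.9),
                                       aspect = c(1.6, 2.6))), "0.85")
  expect_error(scene_config(adult = list(count = 1, body_temp_c = c(13, 16),
                                         area_m2 = c(0.5, 3.0),
                                         aspect = c(1.8, 2.8))), "adult")
})
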