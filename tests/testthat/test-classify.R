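poly_row <- function(A, Tm, R) {
  tibble::tibble(area_m2 = A, mean_temp_c = Tm, chull_ratio = R)
}

test_that("rule set reproduces the documented example polygons", {
  cx <- classification_params(mode = "complex")
  sm <- classification_params(mode = "simplified")
  lab <- function(p, A, Tm, R) classify_seals(poly_row(A, Tm, R), p)$label
  expect_identical(lab(cx, 0.5, 8, 0.9), "individual_yoy")
  expect_identical(lab(cx, 2.0, 12, 0.9), "individual_adult")
  expect_identical(lab(cx, 4.2, 12, 0.6), "adult_aggregation")
  expect_identical(lab(sm, 4.2, 12, 0.6), "adult_aggregation")
  expect_identical(lab(cx, 5.0, 12, 0.95), "unclassified")
  expect_identical(lab(sm, 5.0, 12, 0.95), "unclassified")
  # warm polygon in the 0.65-0.85 band: the two modes disagree
  expect_identical(lab(cx, 0.75, 11, 0.9), "individual_adult")
  expect_identical(lab(sm, 0.75, 11, 0.9), "individual_yoy")
})

test_that("every printed boundary matches a literal transcription of the rules", {
  eps <- 1e-6
  areas <- c(0.65 - eps, 0.65, 0.65 + eps, 0.85 - eps, 0.85, 0.85 + eps,
             3.5 - eps, 3.5, 3.5 + eps, 0.3, 1.2, 5)
  ratios <- c(0.75 - eps, 0.75, 0.75 + eps, 0.8 - eps, 0.8, 0.8 + eps,
              0.5, 0.95)
  temps <- c(10 - eps, 10, 10 + eps, 8, 12)
  for (mode in c("complex", "simplified")) {
    p <- classification_params(mode = mode)
    grid <- expand.grid(A = areas, R = ratios, Tm = temps)
    got <- classify_seals(
      tibble::tibble(area_m2 = grid$A, mean_temp_c = grid$Tm,
                     chull_ratio = grid$R), p)$label
    want <- mapply(oracle_label, grid$A, grid$R, grid$Tm,
                   MoreArgs = list(mode = mode))
    expect_identical(got, unname(want))
  }
})

test_that("boundary audit holds under a temperature offset", {
  p <- offset_temperature(classification_params(mode = "complex"), -3.5)
  eps <- 1e-6
  grid <- expand.grid(A = c(0.3, 0.65, 0.75, 0.85, 1.2, 3.5, 5),
                      R = c(0.7, 0.8 - eps, 0.8 + eps, 0.95),
                      Tm = c(6.5 - eps, 6.5, 6.5 + eps, 4, 9))
  got <- classify_seals(
    tibble::tibble(area_m2 = grid$A, mean_temp_c = grid$Tm,
                   chull_ratio = grid$R), p)$label
  want <- mapply(oracle_label, grid$A, grid$R, grid$Tm,
                 MoreArgs = list(mode = "complex", Tstar = 6.5))
  expect_identical(got, unname(want))
})

test_that("temperature offsets compose additively and default from the site threshold", {
  p <- classification_params(mode = "complex")
  expect_identical(offset_temperature(p, 0), p)
  p2 <- offset_temperature(p, -3.5)
  expect_equal(p2$temp_split_c + p2$temp_offset_c, 6.5)
  expect_equal(offset_temperature(offset_temperature(p, -2), -1.5)$temp_offset_c,
               p2$temp_offset_c)
  # a prediction-site threshold implies the offset automatically
  saddle <- classification_params(mode = "complex", detect_threshold_c = 5.5)
  expect_equal(saddle$temp_offset_c, -3.5)
  # but simplified mode carries no temperature term
  expect_equal(classification_params(mode = "simplified",
                                     detect_threshold_c = 5.5)$temp_offset_c, 0)
})

test_that("modes agree away from the warm 0.65-0.85 band", {
  set.seed(12)
  A <- c(runif(200, 0.05, 0.65 - 1e-9), runif(200, 0.85 + 1e-9, 6))
  R <- runif(400)
  Tm <- runif(400, 4, 18)
  cx <- classify_seals(tibble::tibble(area_m2 = A, mean_temp_c = Tm,
                                      chull_ratio = R),
                       classification_params(mode = "complex"))$label
  sm <- classify_seals(tibble::tibble(area_m2 = A, mean_temp_c = Tm,
                                      chull_ratio = R),
                       classification_params(mode = "simplified"))$label
  # outside the band the complex temperature clause can never fire
  expect_identical(cx, sm)
})

test_that("classification rejects malformed inputs and parameters", {
  expect_error(classify_seals(tibble::tibble(area_m2 = 1), classification_params()),
               "lack")
  expect_error(classify_seals(poly_row(NA, 10, 0.9), classification_params()),
               "unset")
  expect_error(classification_params(yoy_small_area_m2 = 0.9), "yoy_small")
  expect_error(classification_params(ratio_yoy_agg_max = 0.9,
                                     ratio_individual_min = 0.8), "ratio")
})
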