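test_that("count summaries add up and refuse unsplit aggregations", {
  expect_identical(count_summary(empty <- square_det(1, "individual_yoy", 0, 0)[0, ]),
                   tibble::tibble(n_yoy = 0L, n_adult = 0L, n_total = 0L))
  det <- dplyr::bind_rows(
    square_det(1, "individual_yoy", 0, 0), square_det(2, "individual_yoy", 2, 0),
    square_det(3, "individual_yoy", 4, 0), square_det(4, "individual_adult", 0, 2),
    square_det(5, "individual_adult", 2, 2), square_det(6, "unclassified", 4, 2))
  cs <- count_summary(det)
  expect_identical(cs$n_yoy, 3L)
  expect_identical(cs$n_adult, 2L)
  expect_identical(cs$n_total, 5L)
  agg <- square_det(7, "adult_aggregation", 6, 6)
  expect_error(count_summary(dplyr::bind_rows(det, agg)), "split")
})

test_that("snapping honours the radius and is idempotent", {
  det <- square_det(1, "individual_adult", 0, 0, side = 1)
  pts <- pts_tbl(x = c(0.5, 1.3, 1.6, -0.2), y = c(0.5, 0.5, 0.5, -0.2),
                 label = rep("adult", 4))
  sn <- snap_points(pts, det, snap_radius_m = 0.5)
  # inside: untouched
  expect_equal(unlist(sn[1, c("x", "y")]), c(x = 0.5, y = 0.5))
  expect_false(sn$snapped[1])
  # 0.3 m out: moved onto the boundary, displacement <= 0.3 m
  expect_true(sn$snapped[2])
  expect_equal(unlist(sn[2, c("x", "y")]), c(x = 1, y = 0.5))
  expect_lte(sqrt((sn$x[2] - 1.3)^2 + (sn$y[2] - 0.5)^2), 0.3 + 1e-9)
  # 0.6 m out: unchanged
  expect_false(sn$snapped[3])
  expect_equal(sn$x[3], 1.6)
  # corner case: snapped to the nearest corner
  expect_true(sn$snapped[4])
  expect_equal(unlist(sn[4, c("x", "y")]), c(x = 0, y = 0))
  # idempotent
  sn2 <- snap_points(sn, det, snap_radius_m = 0.5)
  expect_equal(sn2$x, sn$x)
  expect_equal(sn2$y, sn$y)
  expect_false(any(sn2$snapped))
})

test_that("ties between equally near polygons go to the lowest id", {
  det <- dplyr::bind_rows(square_det(2, "individual_adult", 2, 0),
                          square_det(1, "individual_adult", -3, 0))
  # point exactly midway between the two squares' facing edges
  pts <- pts_tbl(x = 0, y = 0.5, label = "adult")
  sn <- snap_points(pts, det, snap_radius_m = 5)
  expect_equal(sn$x, -2)  # snapped to polygon id 1
})

test_that("accuracy table reproduces the documented toy joins", {
  yoy_poly <- square_det(1, "individual_yoy", 0, 0)
  n_of <- function(tab, cl, cat) tab$n[tab$class == cl & tab$category == cat]

  # one YOY point inside one YOY polygon: a single true positive
  tab <- accuracy_assessment(pts_tbl(0.5, 0.5, "yoy"), yoy_poly)
  expect_identical(n_of(tab, "yoy", "true_positive"), 1L)
  expect_identical(sum(tab$n), 1L)

  # one YOY point inside an adult polygon without parent: class confusion
  tab <- accuracy_assessment(pts_tbl(0.5, 0.5, "yoy"),
                             square_det(1, "individual_adult", 0, 0))
  expect_identical(n_of(tab, "adult", "confused_with_other_class"), 1L)

  # same, but the polygon came out of an aggregation
  tab <- accuracy_assessment(pts_tbl(0.5, 0.5, "yoy"),
                             square_det(1, "individual_adult", 0, 0,
                                        parent_id = 99L))
  expect_identical(n_of(tab, "adult", "confused_with_aggregation_derived"), 1L)

  # an adult point in no polygon is missed by the model
  tab <- accuracy_assessment(pts_tbl(5, 5, "adult"), yoy_poly)
  expect_identical(n_of(tab, "adult", "missed_by_model"), 1L)
  expect_identical(n_of(tab, "yoy", "not_detected_by_humans"), 1L)

  # a polygon holding one point of each class is an adult/YOY pair
  tab <- accuracy_assessment(pts_tbl(c(0.3, 0.7), c(0.5, 0.5),
                                     c("adult", "yoy")), yoy_poly)
  expect_identical(n_of(tab, "yoy", "confused_with_adult_yoy_pair"), 1L)
  expect_identical(n_of(tab, "yoy", "true_positive"), 0L)
})

test_that("accuracy table conserves predictions and points", {
  set.seed(14)
  labs <- sample(c("individual_yoy", "individual_adult"), 12, replace = TRUE)
  det <- dplyr::bind_rows(lapply(1:12, function(i)
    square_det(i, labs[i], 3 * ((i - 1) %% 4), 3 * ((i - 1) %/% 4))))
  pts <- pts_tbl(x = runif(30, -1, 12), y = runif(30, -1, 9),
                 label = sample(c("adult", "yoy"), 30, replace = TRUE))
  pts <- snap_points(pts, det)
  tab <- accuracy_assessment(pts, det)
  pred_cats <- c("true_positive", "confused_with_other_class",
                 "confused_with_aggregation_derived",
                 "confused_with_adult_yoy_pair", "not_detected_by_humans")
  for (cl in c("yoy", "adult")) {
    n_pred <- sum(labs == paste0("individual_", cl))
    rows <- tab[tab$class == cl & tab$category %in% pred_cats, ]
    expect_identical(sum(rows$n), n_pred)
    if (n_pred > 0) expect_equal(sum(rows$proportion), 1, tolerance = 1e-9)
  }
  # every point lands in exactly one polygon's tally or is missed; since a
  # polygon can hold several points, bound rather than equate the join side
  n_missed <- sum(tab$n[tab$category == "missed_by_model"])
  n_joined <- nrow(pts) - n_missed
  n_pred_hits <- sum(tab$n[tab$category %in% pred_cats[1:4]])
  expect_gte(n_joined, n_pred_hits)
})

test_that("points round-trip through CSV and GeoJSON", {
  pts <- pts_tbl(x = c(1.25, 2.5), y = c(3.5, 4.75), label = c("adult", "yoy"))
  for (ext in c("csv", "geojson")) {
    p <- file.path(tempdir(), paste0("pts.", ext))
    write_points(pts, p)
    back <- read_points(p)
    expect_equal(back$x, pts$x)
    expect_equal(back$y, pts$y)
    expect_identical(back$label, pts$label)
  }
  bad <- file.path(tempdir(), "bad.csv")
  utils::write.csv(data.frame(id = 1, x = 0, y = 0, label = "pup"), bad,
                   row.names = FALSE)
  expect_error(read_points(bad), "adult")
})
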