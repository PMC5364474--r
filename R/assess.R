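# Accuracy assessment against human annotation points: GPS snap, spatial
# join, per-class confusion tabulation and count summaries.

#' Summarise individual seal counts
#'
#' Total counts are the sums of individual YOY and individual adult
#' polygons; aggregation labels must already have been split into
#' individuals, and unclassified polygons are excluded.
#'
#' @param detections A detection tibble with individual labels (post
#'   splitting).
#' @return A one-row tibble with `n_yoy`, `n_adult`, `n_total`.
#' @export
count_summary <- function(detections) {
  if (any(detections$label %in% c("yoy_aggregation", "adult_aggregation")))
    stop("aggregation labels remain; run split_aggregations() before ",
         "counting", call. = FALSE)
  n_yoy <- sum(detections$label == "individual_yoy", na.rm = TRUE)
  n_adult <- sum(detections$label == "individual_adult", na.rm = TRUE)
  tibble::tibble(n_yoy = n_yoy, n_adult = n_adult,
                 n_total = n_yoy + n_adult)
}

point_class_of <- function(polygon_label) {
  c(individual_yoy = "yoy", individual_adult = "adult",
    yoy_aggregation = "yoy", adult_aggregation = "adult")[[polygon_label]]
}

#' Snap annotation points onto nearby prediction polygons
#'
#' Corrects minor GPS error before the spatial join: a point already
#' inside (or on the boundary of) any prediction polygon is left alone; a
#' point within `snap_radius_m` of its nearest polygon boundary is moved
#' to the closest location on that polygon; points farther than the radius
#' from every polygon are unchanged. Ties between equally near polygons go
#' to the lowest polygon id. The operation is idempotent.
#'
#' @param points Tibble with columns `id`, `x`, `y`, `label`.
#' @param detections A detection tibble.
#' @param snap_radius_m Snap radius in metres (default 0.5).
#' @return The points tibble with adjusted coordinates and a logical
#'   `snapped` column.
#' @export
snap_points <- function(points, detections, snap_radius_m = 0.5) {
  stopifnot(snap_radius_m >= 0)
  points$snapped <- FALSE
  if (nrow(points) == 0L || nrow(detections) == 0L) return(points)
  ord <- order(detections$id)
  geoms <- detections$geometry[ord]
  for (i in seq_len(nrow(points))) {
    px <- points$x[i]; py <- points$y[i]
    inside <- FALSE
    for (rings in geoms) {
      if (points_in_rings(px, py, rings)) { inside <- TRUE; break }
    }
    if (inside) next
    best_d <- Inf; best <- NULL
    for (rings in geoms) {
      bb <- rings_bbox(rings)
      if (px < bb["xmin"] - best_d || px > bb["xmax"] + best_d ||
          py < bb["ymin"] - best_d || py > bb["ymax"] + best_d) next
      np <- nearest_on_rings(px, py, rings)
      if (np$dist < best_d) { best_d <- np$dist; best <- np }
    }
    if (!is.null(best) && best_d <= snap_radius_m) {
      points$x[i] <- best$x; points$y[i] <- best$y
      points$snapped[i] <- TRUE
    }
  }
  points
}

#' Accuracy assessment of prediction polygons against annotation points
#'
#' Spatially joins (snapped) human annotation points with individual
#' prediction polygons and tabulates, per predicted class, the outcome of
#' every polygon:
#'
#' * `true_positive` — the polygon contains a point of its own class;
#' * `confused_with_other_class` — it contains only point(s) of the other
#'   class and was not derived from an aggregation;
#' * `confused_with_aggregation_derived` — as above but the polygon was
#'   carved out of an aggregation (`parent_id` set), the typical
#'   mother/pup confusion inside YOY aggregations;
#' * `confused_with_adult_yoy_pair` — it contains one adult and one YOY
#'   point (an adult female adjacent to her pup merged into one object);
#' * `not_detected_by_humans` — it contains no point at all.
#'
#' The pair category takes precedence over `true_positive`: a polygon
#' covering one point of each class is a single object spanning two
#' animals, not a confirmed single detection.
#'
#' Each polygon falls in exactly one category, so per class the five
#' counts sum to the number of predictions and the reported proportions
#' (count / predictions of that class) sum to 1. Human points contained in
#' no polygon are tallied separately as `missed_by_model` per point class.
#'
#' @param points Snapped annotation points (see [snap_points()]).
#' @param detections Individual prediction polygons (post splitting).
#' @return A tibble with columns `class` (`"yoy"`/`"adult"`), `category`,
#'   `n` and `proportion` (`NA` for the point-side `missed_by_model`
#'   rows).
#' @export
accuracy_assessment <- function(points, detections) {
  if (any(detections$label %in% c("yoy_aggregation", "adult_aggregation")))
    stop("aggregation labels remain; run split_aggregations() first",
         call. = FALSE)
  dets <- detections[detections$label %in%
                       c("individual_yoy", "individual_adult"), , drop = FALSE]
  dets <- dets[order(dets$id), , drop = FALSE]
  n_det <- nrow(dets)
  # assign each point to the first (lowest-id) polygon containing it
  pt_poly <- rep(NA_integer_, nrow(points))
  if (nrow(points) > 0L && n_det > 0L) {
    for (j in seq_len(n_det)) {
      rings <- dets$geometry[[j]]
      bb <- rings_bbox(rings)
      cand <- which(is.na(pt_poly) &
                      points$x >= bb["xmin"] & points$x <= bb["xmax"] &
                      points$y >= bb["ymin"] & points$y <= bb["ymax"])
      if (length(cand) == 0L) next
      hit <- points_in_rings(points$x[cand], points$y[cand], rings)
      pt_poly[cand[hit]] <- j
    }
  }
  categories <- c("true_positive", "confused_with_other_class",
                  "confused_with_aggregation_derived",
                  "confused_with_adult_yoy_pair", "not_detected_by_humans")
  tab <- matrix(0L, nrow = 2L, ncol = length(categories),
                dimnames = list(c("yoy", "adult"), categories))
  for (j in seq_len(n_det)) {
    own <- point_class_of(dets$label[j])
    inside <- points$label[which(pt_poly == j)]
    # the pair test precedes the true-positive test: a polygon holding one
    # point of each class is one object covering two animals (a mis-split),
    # not a confirmed single detection, even though one point matches
    cat_j <-
      if (length(inside) == 0L) "not_detected_by_humans"
      else if (all(c("adult", "yoy") %in% inside)) "confused_with_adult_yoy_pair"
      else if (any(inside == own)) "true_positive"
      else if (!is.na(dets$parent_id[j])) "confused_with_aggregation_derived"
      else "confused_with_other_class"
    tab[own, cat_j] <- tab[own, cat_j] + 1L
  }
  totals <- rowSums(tab)
  pred_rows <- purrr::map_dfr(c("yoy", "adult"), function(cl) {
    tibble::tibble(class = cl, category = categories,
                   n = as.integer(tab[cl, ]),
                   proportion = if (totals[[cl]] > 0)
                     as.numeric(tab[cl, ]) / totals[[cl]]
                   else rep(NA_real_, length(categories)))
  })
  missed <- vapply(c("yoy", "adult"), function(cl)
    sum(is.na(pt_poly) & points$label == cl), 0L)
  miss_rows <- tibble::tibble(class = c("yoy", "adult"),
                              category = "missed_by_model",
                              n = as.integer(missed),
                              proportion = NA_real_)
  dplyr::bind_rows(pred_rows, miss_rows)
}
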