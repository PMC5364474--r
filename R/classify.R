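# Rule-based classification of warm polygons into individual
# young-of-the-year (YOY), individual adults, YOY aggregations and adult
# aggregations, using planar area (m^2), mean temperature (degC) and
# convex-hull solidity. Two variants exist: the "complex" model uses
# temperature to separate warm large YOY from small adults; the
# "simplified" model drops temperature and uses area and shape only.

#' Classification parameter set
#'
#' All thresholds of the rule-based seal classifier, with defaults as
#' trained at the reference colony. The temperature split used by the
#' complex model is `temp_split_c + temp_offset_c`; when the model is moved
#' to a site with a different detection threshold, the split is offset by
#' the difference in site thresholds (e.g. `5.5 - 9 = -3.5` degC), which
#' [classification_params()] applies automatically unless `temp_offset_c`
#' is given explicitly.
#'
#' @param mode `"complex"` (area + shape + temperature) or `"simplified"`
#'   (area + shape only).
#' @param detect_threshold_c Lower thermal detection boundary in degC
#'   (inclusive); 9 at the training site, 5.5 at the colder prediction
#'   site.
#' @param yoy_area_max_m2 Maximum planar area of an individual YOY (0.85).
#' @param yoy_small_area_m2 Area below which a polygon is a YOY regardless
#'   of temperature (0.65).
#' @param adult_area_max_m2 Maximum planar area of an individual adult
#'   (3.5).
#' @param ratio_individual_min Minimum convex-hull solidity of an
#'   individual adult (0.8).
#' @param ratio_yoy_agg_max Maximum solidity of a small YOY aggregation
#'   (0.75).
#' @param temp_split_c YOY/adult temperature split in degC (10; complex
#'   mode only).
#' @param temp_offset_c Additive offset applied to `temp_split_c`. Default:
#'   `detect_threshold_c - 9` when a non-default threshold is used in
#'   complex mode, else 0.
#' @param connectivity Clustering connectivity carried through the
#'   pipeline (4 or 8).
#' @return A list of class `classification_params`.
#' @examples
#' classification_params()                          # training-site defaults
#' classification_params(detect_threshold_c = 5.5)  # offset -3.5 applied
#' @export
classification_params <- function(mode = c("complex", "simplified"),
                                  detect_threshold_c = 9,
                                  yoy_area_max_m2 = 0.85,
                                  yoy_small_area_m2 = 0.65,
                                  adult_area_max_m2 = 3.5,
                                  ratio_individual_min = 0.8,
                                  ratio_yoy_agg_max = 0.75,
                                  temp_split_c = 10,
                                  temp_offset_c = NULL,
                                  connectivity = 4) {
  mode <- match.arg(mode)
  if (is.null(temp_offset_c))
    temp_offset_c <- if (mode == "complex") detect_threshold_c - 9 else 0
  p <- list(mode = mode, detect_threshold_c = detect_threshold_c,
            yoy_area_max_m2 = yoy_area_max_m2,
            yoy_small_area_m2 = yoy_small_area_m2,
            adult_area_max_m2 = adult_area_max_m2,
            ratio_individual_min = ratio_individual_min,
            ratio_yoy_agg_max = ratio_yoy_agg_max,
            temp_split_c = temp_split_c, temp_offset_c = temp_offset_c,
            connectivity = connectivity)
  validate_params(p)
  structure(p, class = "classification_params")
}

validate_params <- function(p) {
  with(p, {
    if (!(0 < yoy_small_area_m2 && yoy_small_area_m2 < yoy_area_max_m2 &&
          yoy_area_max_m2 < adult_area_max_m2))
      stop("need 0 < yoy_small_area_m2 < yoy_area_max_m2 < adult_area_max_m2",
           call. = FALSE)
    if (!(0 < ratio_yoy_agg_max && ratio_yoy_agg_max <= ratio_individual_min &&
          ratio_individual_min <= 1))
      stop("need 0 < ratio_yoy_agg_max <= ratio_individual_min <= 1",
           call. = FALSE)
    if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8",
                                         call. = FALSE)
  })
  invisible(TRUE)
}

#' @export
print.classification_params <- function(x, ...) {
  cat(sprintf("<classification_params> mode=%s, detect >= %.2f degC\n",
              x$mode, x$detect_threshold_c))
  cat(sprintf("  areas (m2): yoy <= %.2f (uncond < %.2f), adult <= %.2f\n",
              x$yoy_area_max_m2, x$yoy_small_area_m2, x$adult_area_max_m2))
  cat(sprintf("  solidity: individual > %.2f, small yoy agg < %.2f\n",
              x$ratio_individual_min, x$ratio_yoy_agg_max))
  cat(sprintf("  temperature split: %.1f %+.1f = %.1f degC\n",
              x$temp_split_c, x$temp_offset_c,
              x$temp_split_c + x$temp_offset_c))
  invisible(x)
}

#' Shift the temperature split of a parameter set
#'
#' Adds `delta` to `temp_offset_c`, leaving every other threshold
#' unchanged. Used to carry the classifier across sites with different
#' ambient conditions by offsetting the YOY/adult temperature split by the
#' difference in site detection thresholds.
#'
#' @param params A [classification_params()] object.
#' @param delta Offset increment in degC (may be negative).
#' @return The adjusted `classification_params`.
#' @export
offset_temperature <- function(params, delta) {
  stopifnot(inherits(params, "classification_params"), is.finite(delta))
  params$temp_offset_c <- params$temp_offset_c + delta
  params
}

#' Classify warm polygons
#'
#' Assigns each detection one of `individual_yoy`, `individual_adult`,
#' `yoy_aggregation`, `adult_aggregation` or `unclassified`, evaluating the
#' rule set in that fixed precedence order (first match wins; individuals
#' are claimed before aggregations, which are the residual sent to
#' splitting). With area `A` (m^2), solidity `R`, mean temperature `T` and
#' split `T* = temp_split_c + temp_offset_c`:
#'
#' * individual YOY — complex: `(A <= 0.85 & T < T*) | A < 0.65`;
#'   simplified: `A <= 0.85`.
#' * individual adult — complex:
#'   `(0.65 < A <= 3.5 & R > 0.8 & T > T*) | (0.85 < A <= 3.5 & R > 0.8)`;
#'   simplified: `0.85 < A <= 3.5 & R > 0.8`.
#' * YOY aggregation (both modes):
#'   `(0.65 < A < 0.85 & R < 0.75) | (0.85 < A < 3.5 & R < 0.8)`.
#' * adult aggregation (both modes): `A > 3.5 & R < 0.8`.
#'
#' Strict and non-strict inequalities are applied exactly as stated,
#' including the asymmetry between the individual (`<= 0.85`) and
#' aggregation (`< 0.85`) bounds. Polygons matching no rule (e.g. large
#' compact objects, or boundary values such as `R == 0.8`) are labelled
#' `unclassified` and excluded from counts rather than silently dropped.
#'
#' @param detections A detection tibble (see [detect_seals()]), or any
#'   data frame with `area_m2`, `mean_temp_c`, `chull_ratio`.
#' @param params A [classification_params()] object.
#' @return The tibble with its `label` column filled in.
#' @export
classify_seals <- function(detections, params = classification_params()) {
  stopifnot(inherits(params, "classification_params"))
  need <- c("area_m2", "mean_temp_c", "chull_ratio")
  miss <- setdiff(need, names(detections))
  if (length(miss) > 0L)
    stop("detections lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(detections$area_m2)) || any(is.na(detections$chull_ratio)) ||
      (params$mode == "complex" && any(is.na(detections$mean_temp_c))))
    stop("detections have unset attributes; run the detector first",
         call. = FALSE)
  A <- detections$area_m2
  R <- detections$chull_ratio
  Tm <- detections$mean_temp_c
  p <- params
  Tstar <- p$temp_split_c + p$temp_offset_c
  yoy <- if (p$mode == "complex") {
    (A <= p$yoy_area_max_m2 & Tm < Tstar) | A < p$yoy_small_area_m2
  } else {
    A <= p$yoy_area_max_m2
  }
  adult <- if (p$mode == "complex") {
    (A > p$yoy_small_area_m2 & A <= p$adult_area_max_m2 &
       R > p$ratio_individual_min & Tm > Tstar) |
      (A > p$yoy_area_max_m2 & A <= p$adult_area_max_m2 &
         R > p$ratio_individual_min)
  } else {
    A > p$yoy_area_max_m2 & A <= p$adult_area_max_m2 &
      R > p$ratio_individual_min
  }
  yoy_agg <- (A > p$yoy_small_area_m2 & A < p$yoy_area_max_m2 &
                R < p$ratio_yoy_agg_max) |
             (A > p$yoy_area_max_m2 & A < p$adult_area_max_m2 &
                R < p$ratio_individual_min)
  adult_agg <- A > p$adult_area_max_m2 & R < p$ratio_individual_min
  label <- dplyr::case_when(
    yoy ~ "individual_yoy",
    adult ~ "individual_adult",
    yoy_agg ~ "yoy_aggregation",
    adult_agg ~ "adult_aggregation",
    TRUE ~ "unclassified")
  detections$label <- label
  detections
}

class_levels <- c("individual_yoy", "individual_adult",
                  "yoy_aggregation", "adult_aggregation", "unclassified")
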