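# End-to-end census pipeline: mask -> threshold -> cluster -> polygonise
# -> classify -> split aggregations -> count.

#' Run the full seal census pipeline
#'
#' Executes the complete detection flow on a thermal raster: optional
#' exclusion masking, inclusive thresholding at
#' `params$detect_threshold_c`, connected-component clustering,
#' polygonisation with area/temperature/solidity attributes, rule-based
#' classification, high-pass splitting of aggregation polygons into
#' individuals, and count summarisation. Deterministic for fixed inputs.
#'
#' @param raster A [thermal_raster()].
#' @param params A [classification_params()].
#' @param mask Optional [exclusion_mask()].
#' @param kernel A [high_pass_kernel()] for aggregation splitting.
#' @param response_min Post-filter selection threshold (strict `>`).
#' @return A `seal_census` object: list with
#'   * `detections` — tibble of individual polygons (split children carry
#'     `parent_id`),
#'   * `unclassified` — tibble of polygons matching no rule,
#'   * `aggregates_found` — number of aggregation polygons before
#'     splitting,
#'   * `counts` — one-row tibble `n_yoy`, `n_adult`, `n_total`,
#'   * `stage_log` — per-stage object counts,
#'   * `params`, `kernel` — configuration echo.
#' @examples
#' sc <- generate_scene(scene_config(yoy = list(count = 3,
#'   body_temp_c = c(12, 14), area_m2 = c(0.3, 0.6), aspect = c(1.6, 2.4)),
#'   adult = list(count = 2, body_temp_c = c(13, 15), area_m2 = c(1.5, 2.5),
#'   aspect = c(2, 2.6)), extent_m = c(20, 20), seed = 3))
#' cen <- run_pipeline(sc$raster, classification_params(mode = "simplified"))
#' cen$counts
#' @export
run_pipeline <- function(raster, params = classification_params(),
                         mask = NULL, kernel = high_pass_kernel(),
                         response_min = 0) {
  stopifnot(inherits(raster, "thermal_raster"),
            inherits(params, "classification_params"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(mask))
    raster <- stage("mask", apply_exclusion_mask(raster, mask))
  sel <- stage("threshold", select_hot_pixels(raster, params$detect_threshold_c))
  clusters <- stage("cluster", extract_clusters(sel, params$connectivity))
  detections <- stage("polygonize", {
    if (length(clusters) == 0L) empty_detections() else
      dplyr::bind_rows(purrr::imap(clusters, function(cl, i)
        polygonize_cluster(cl, raster, id = i)))
  })
  detections <- stage("classify", classify_seals(detections, params))
  n_agg <- sum(detections$label %in% c("yoy_aggregation", "adult_aggregation"))
  split_det <- stage("split",
    split_aggregations(detections, raster, params = params, kernel = kernel,
                       response_min = response_min))
  unclassified <- split_det[split_det$label == "unclassified", , drop = FALSE]
  individuals <- split_det[split_det$label %in%
                             c("individual_yoy", "individual_adult"), ,
                           drop = FALSE]
  counts <- stage("count", count_summary(individuals))
  stage_log <- tibble::tibble(
    stage = c("selected_pixels", "clusters", "classified_polygons",
              "aggregations", "individuals", "unclassified"),
    n = c(sum(sel), length(clusters), nrow(detections), n_agg,
          nrow(individuals), nrow(unclassified)))
  structure(list(detections = individuals, unclassified = unclassified,
                 aggregates_found = n_agg, counts = counts,
                 stage_log = stage_log, params = params, kernel = kernel),
            class = "seal_census")
}

#' @export
print.seal_census <- function(x, ...) {
  cat("<seal_census>\n")
  cat(sprintf("  %d individuals (%d YOY, %d adult); %d aggregation(s) split; %d unclassified\n",
              x$counts$n_total, x$counts$n_yoy, x$counts$n_adult,
              x$aggregates_found, nrow(x$unclassified)))
  cat(sprintf("  mode %s, detect >= %.2f degC\n",
              x$params$mode, x$params$detect_threshold_c))
  invisible(x)
}

#' Tidy a seal census
#'
#' `tidy()` returns the per-polygon detection table (one row per
#' individual seal prediction); `glance()` returns a one-row summary.
#'
#' @param x A `seal_census` object from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy seal_census
#' @export
tidy.seal_census <- function(x, ...) {
  dplyr::select(x$detections, -dplyr::any_of("cells"))
}

#' @rdname tidy.seal_census
#' @method glance seal_census
#' @export
glance.seal_census <- function(x, ...) {
  tibble::tibble(n_yoy = x$counts$n_yoy, n_adult = x$counts$n_adult,
                 n_total = x$counts$n_total,
                 aggregates_found = x$aggregates_found,
                 n_unclassified = nrow(x$unclassified),
                 mode = x$params$mode,
                 detect_threshold_c = x$params$detect_threshold_c)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
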