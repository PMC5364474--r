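# Seeded synthetic thermal colony scenes with ground truth.
#
# Each seal is a smooth elliptical "thermal dome": a capped paraboloid
# rising from ambient to the body's peak temperature, emulating a warm
# body blurred by sensor response. Domes are composed into the background
# with a pointwise maximum, so the detection-threshold level set of the
# scene is exactly the union of the per-seal footprint ellipses: isolated
# seals threshold to single compact polygons, and aggregation members -
# placed close enough for their footprint ellipses to overlap - merge into
# one polygon while each member keeps a distinct warm core. Cool seams are
# carved along the bisector between adjacent aggregation members, giving
# the negative high-pass response that instance splitting relies on.

#' Synthetic scene configuration
#'
#' Parameters of the synthetic thermal colony generator. Defaults emulate
#' a mid-winter grey seal breeding colony as surveyed at 8 cm GSD: cold
#' ground a few degrees above freezing with mild spatial noise and some
#' warmer landscape patches below the detection threshold; small, cooler
#' young-of-the-year (YOY) and larger, warmer adults with planar areas
#' inside the classifier's individual bands; optional multi-member
#' aggregations with distinct warm cores.
#'
#' @param gsd_m Ground sampling distance (m per pixel).
#' @param extent_m Scene width and height in metres, `c(w, h)`.
#' @param ambient_mean_c,ambient_sd_c Mean and spatial standard deviation
#'   of the ambient background (degC).
#' @param detect_threshold_c Detection threshold the scene is built
#'   against: seal footprint areas are defined at this temperature level,
#'   and warm landscape patches stay below it.
#' @param warm_patches List with `count`, `radius_m = c(min, max)`,
#'   `excess_c = c(min, max)`: dome-shaped landscape confounders whose
#'   peak stays `ambient_mean_c + excess_c`, below the threshold.
#' @param yoy,adult Per-class seal specs: list with `count`,
#'   `body_temp_c = c(min, max)` (peak temperature), `area_m2 = c(min,
#'   max)` (planar footprint area at the threshold) and `aspect = c(min,
#'   max)` (footprint ellipse aspect ratio).
#' @param aggregations List with `count`, `members = c(min, max)` (members
#'   per aggregation), `member_class` (`"adult"` or `"yoy"`),
#'   `core_spacing_px` (distance between adjacent member cores, pixels),
#'   `core_excess_c` (required thermal prominence of each member's core
#'   above the neighbouring bodies at that point; placements violating it
#'   are redrawn, so every member is a distinct warm core),
#'   `seam_depression_c` (depth of the cool seam carved along the
#'   equal-temperature contact line of every overlapping pair, degC) and
#'   `seam_width_c` (its Gaussian half-width, expressed in degC of
#'   dome-value difference). Member body temperature, area and aspect come
#'   from the member class spec.
#' @param min_gap_px Minimum clear pixels between distinct footprints
#'   (isolated seals and aggregations), so nothing merges by accident.
#' @param seed Integer seed; identical config and seed give a
#'   bit-identical scene.
#' @param crs CRS identifier stamped on the raster.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(gsd_m = 0.08,
                         extent_m = c(50, 50),
                         ambient_mean_c = 2,
                         ambient_sd_c = 0.6,
                         detect_threshold_c = 9,
                         warm_patches = list(count = 3,
                                             radius_m = c(0.4, 1.2),
                                             excess_c = c(3, 6)),
                         yoy = list(count = 40,
                                    body_temp_c = c(12, 14),
                                    area_m2 = c(0.25, 0.60),
                                    aspect = c(1.6, 2.6)),
                         adult = list(count = 20,
                                      body_temp_c = c(13, 16),
                                      area_m2 = c(1.2, 3.0),
                                      aspect = c(1.8, 2.8)),
                         aggregations = list(count = 0,
                                             members = c(3, 5),
                                             member_class = "adult",
                                             core_spacing_px = 8,
                                             core_excess_c = 1.5,
                                             seam_depression_c = 2,
                                             seam_width_c = 1),
                         min_gap_px = 2,
                         seed = 1,
                         crs = "EPSG:32620") {
  cfg <- list(gsd_m = gsd_m, extent_m = extent_m,
              ambient_mean_c = ambient_mean_c, ambient_sd_c = ambient_sd_c,
              detect_threshold_c = detect_threshold_c,
              warm_patches = warm_patches, yoy = yoy, adult = adult,
              aggregations = aggregations, min_gap_px = min_gap_px,
              seed = seed, crs = crs)
  if (cfg$yoy$area_m2[2] > 0.85)
    stop("yoy area range must stay <= 0.85 m^2", call. = FALSE)
  if (cfg$adult$area_m2[1] <= 0.85 || cfg$adult$area_m2[2] > 3.5)
    stop("adult area range must lie within (0.85, 3.5] m^2", call. = FALSE)
  counts <- c(cfg$warm_patches$count, cfg$yoy$count, cfg$adult$count,
              cfg$aggregations$count)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  structure(cfg, class = "scene_config")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Paraboloid dome: peak temperature at the centre falling to `base` at
# elliptical radius 1 (semi-axes a0, b0, orientation theta). Returns the
# field with the dome max-composed in.
compose_dome <- function(field, raster, cx, cy, a0, b0, theta, peak, base) {
  g <- raster$gsd_m
  nr <- nrow(field); nc <- ncol(field)
  rad <- max(a0, b0)
  c1 <- max(1L, floor((cx - rad - raster$xmin) / g)); c2 <- min(nc, ceiling((cx + rad - raster$xmin) / g) + 1L)
  r1 <- max(1L, floor((raster$ymax - cy - rad) / g)); r2 <- min(nr, ceiling((raster$ymax - cy + rad) / g) + 1L)
  if (c1 > c2 || r1 > r2) return(field)
  rows <- r1:r2; cols <- c1:c2
  x <- raster$xmin + (cols - 0.5) * g
  y <- raster$ymax - (rows - 0.5) * g
  dx <- outer(rep(1, length(rows)), x - cx)
  dy <- outer(y - cy, rep(1, length(cols)))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  u2 <- (xr / a0)^2 + (yr / b0)^2
  dome <- base + (peak - base) * pmax(1 - u2, 0)
  field[rows, cols] <- pmax(field[rows, cols], dome)
  field
}

# Footprint geometry of a seal dome: semi-axes of the ellipse where the
# dome crosses the detection threshold, plus the dome's zero-level axes.
dome_geometry <- function(area_m2, aspect, peak, base, thr) {
  bf <- sqrt(area_m2 / (pi * aspect))
  af <- aspect * bf
  if (peak > thr && thr > base) {
    ut <- sqrt((peak - thr) / (peak - base))
  } else {
    ut <- sqrt(0.5)  # undetectable seal: scale the dome off its half-max
  }
  list(af = af, bf = bf, a0 = af / ut, b0 = bf / ut)
}

# cells (row/col matrix) whose centres fall inside an ellipse
ellipse_cells <- function(raster, cx, cy, a, b, theta) {
  g <- raster$gsd_m
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  rad <- max(a, b)
  c1 <- max(1L, floor((cx - rad - raster$xmin) / g)); c2 <- min(nc, ceiling((cx + rad - raster$xmin) / g) + 1L)
  r1 <- max(1L, floor((raster$ymax - cy - rad) / g)); r2 <- min(nr, ceiling((raster$ymax - cy + rad) / g) + 1L)
  if (c1 > c2 || r1 > r2) return(cbind(row = integer(0), col = integer(0)))
  cols <- rep(c1:c2, each = r2 - r1 + 1L)
  rows <- rep(r1:r2, times = c2 - c1 + 1L)
  x <- raster$xmin + (cols - 0.5) * g - cx
  y <- raster$ymax - (rows - 0.5) * g - cy
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  hit <- (xr / a)^2 + (yr / b)^2 <= 1
  cbind(row = rows[hit], col = cols[hit])
}

#' Generate a synthetic thermal colony scene
#'
#' Draws a seeded scene from a [scene_config()]: Gaussian ambient
#' background, warm landscape patches, isolated seals and multi-member
#' aggregations, consumed from a single random stream in that order.
#' Isolated footprints are kept at least `min_gap_px` pixels apart;
#' aggregation members are placed on a zig-zag chain with overlapping
#' footprints so they merge into one thresholded polygon whose members
#' remain distinct warm cores separated by carved cool seams.
#'
#' @param cfg A [scene_config()].
#' @return A list with elements `raster` (a [thermal_raster()]) and
#'   `truth`, itself a list of `points` (tibble `id`, `x`, `y`, `label` —
#'   one point per seal at its core) and `seals` (tibble adding `class`,
#'   `area_m2`, `body_temp_c`, `agg_id`).
#' @examples
#' sc <- generate_scene(scene_config(yoy = list(count = 2,
#'   body_temp_c = c(12, 14), area_m2 = c(0.3, 0.6), aspect = c(1.6, 2.4)),
#'   adult = list(count = 1, body_temp_c = c(13, 15), area_m2 = c(1.5, 2.5),
#'   aspect = c(2, 2.6)), extent_m = c(15, 15), seed = 7))
#' nrow(sc$truth$points)
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  withr::with_seed(cfg$seed, generate_scene_impl(cfg))
}

generate_scene_impl <- function(cfg) {
  g <- cfg$gsd_m
  nc <- as.integer(round(cfg$extent_m[1] / g))
  nr <- as.integer(round(cfg$extent_m[2] / g))
  raster <- thermal_raster(matrix(cfg$ambient_mean_c, nr, nc),
                           xmin = 0, ymax = cfg$extent_m[2], gsd_m = g,
                           crs = cfg$crs)
  thr <- cfg$detect_threshold_c

  # 1. background noise
  field <- matrix(stats::rnorm(nr * nc, cfg$ambient_mean_c, cfg$ambient_sd_c),
                  nr, nc)

  # 2. warm landscape patches (peaks below the detection threshold)
  wp <- cfg$warm_patches
  if (wp$count > 0) for (i in seq_len(wp$count)) {
    r <- runif1(wp$radius_m)
    ex <- runif1(wp$excess_c)
    cx <- stats::runif(1, 0, cfg$extent_m[1])
    cy <- stats::runif(1, 0, cfg$extent_m[2])
    field <- compose_dome(field, raster, cx, cy, r, r, 0,
                          peak = cfg$ambient_mean_c + ex,
                          base = cfg$ambient_mean_c)
  }

  occupied <- matrix(FALSE, nr, nc)
  seals <- list()
  seal_id <- 0L
  margin_m <- 1.0
  max_tries <- 200L

  place_isolated <- function(spec, class) {
    for (i in seq_len(spec$count)) {
      peak <- runif1(spec$body_temp_c)
      area <- runif1(spec$area_m2)
      aspect <- runif1(spec$aspect)
      theta <- stats::runif(1, 0, pi)
      geom <- dome_geometry(area, aspect, peak, cfg$ambient_mean_c, thr)
      placed <- FALSE
      lo <- margin_m + geom$af
      hi_x <- cfg$extent_m[1] - margin_m - geom$af
      hi_y <- cfg$extent_m[2] - margin_m - geom$af
      for (try in seq_len(if (hi_x > lo && hi_y > lo) max_tries else 0L)) {
        cx <- stats::runif(1, lo, hi_x)
        cy <- stats::runif(1, lo, hi_y)
        guard <- ellipse_cells(raster, cx, cy,
                               geom$af + cfg$min_gap_px * g,
                               geom$bf + cfg$min_gap_px * g, theta)
        if (nrow(guard) > 0L && !any(occupied[guard])) {
          core <- ellipse_cells(raster, cx, cy, geom$af, geom$bf, theta)
          occupied[guard] <<- TRUE
          field <<- compose_dome(field, raster, cx, cy, geom$a0, geom$b0,
                                 theta, peak, cfg$ambient_mean_c)
          seal_id <<- seal_id + 1L
          seals[[length(seals) + 1L]] <<- tibble::tibble(
            id = seal_id, class = class, x = cx, y = cy, area_m2 = area,
            body_temp_c = peak, agg_id = NA_integer_)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", class, " seal ", i, " after ", max_tries,
             " tries; scene too dense (", spec$count, " x ~",
             signif(mean(spec$area_m2), 2), " m^2 in ",
             cfg$extent_m[1], "x", cfg$extent_m[2], " m)", call. = FALSE)
    }
  }

  # 3. isolated seals, YOY first then adults
  place_isolated(cfg$yoy, "yoy")
  place_isolated(cfg$adult, "adult")

  # 4. aggregations: zig-zag chains of overlapping members with carved seams
  agg <- cfg$aggregations
  if (agg$count > 0) {
    spec <- cfg[[agg$member_class]]
    spacing <- agg$core_spacing_px * g
    for (ai in seq_len(agg$count)) {
      k <- if (length(agg$members) > 1L)
        sample(agg$members[1]:agg$members[2], 1L) else agg$members
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # propose member centres along a zig-zag chain
        # members curl along an arc with a per-huddle turning direction:
        # a consistently curling chain is concave (its hull closes the
        # mouth of the "C"), which is what separates aggregation outlines
        # from compact individual bodies
        phi <- stats::runif(1, 0, 2 * pi)
        curl <- sample(c(-1, 1), 1L)
        ctr <- matrix(NA_real_, k, 2)
        ctr[1, ] <- c(stats::runif(1, margin_m + 2, cfg$extent_m[1] - margin_m - 2),
                      stats::runif(1, margin_m + 2, cfg$extent_m[2] - margin_m - 2))
        if (k > 1L) for (m in 2:k) {
          if (m > 2L) phi <- phi + curl * stats::runif(1, 50, 85) * pi / 180
          ctr[m, ] <- ctr[m - 1, ] + spacing * c(cos(phi), sin(phi))
        }
        # members of one huddle share size and body temperature and are
        # circular: with equal peaks and equal circular footprints the
        # contact between two bodies is exactly the straight bisector,
        # whereas unequal or elongated domes meet along conic loci whose
        # second branch would carve a phantom seam through a single body
        peaks <- rep(runif1(spec$body_temp_c), k)
        areas <- rep(runif1(spec$area_m2), k)
        aspects <- rep(1, k)
        thetas <- rep(0, k)
        geoms <- lapply(seq_len(k), function(m)
          dome_geometry(areas[m], aspects[m], peaks[m], cfg$ambient_mean_c, thr))
        guard <- do.call(rbind, lapply(seq_len(k), function(m)
          ellipse_cells(raster, ctr[m, 1], ctr[m, 2],
                        geoms[[m]]$af + cfg$min_gap_px * g,
                        geoms[[m]]$bf + cfg$min_gap_px * g, thetas[m])))
        pad <- margin_m + max(vapply(geoms, function(ge) ge$af, 0))
        in_bounds <- all(ctr[, 1] > pad) && all(ctr[, 1] < cfg$extent_m[1] - pad) &&
          all(ctr[, 2] > pad) && all(ctr[, 2] < cfg$extent_m[2] - pad)
        if (!in_bounds || nrow(guard) == 0L || any(occupied[guard])) next
        # members must actually merge: adjacent footprints overlap
        merged <- all(vapply(seq_len(k - 1L), function(m)
          spacing < 0.9 * (min(geoms[[m]]$af, geoms[[m]]$bf) +
                           min(geoms[[m + 1L]]$af, geoms[[m + 1L]]$bf)), TRUE))
        if (!merged) next
        # every member must remain a distinct warm core: its peak has to
        # stand at least core_excess_c above all neighbouring bodies there
        domes <- lapply(seq_len(k), function(m)
          list(ctr = ctr[m, ], geom = geoms[[m]], theta = thetas[m],
               peak = peaks[m]))
        prominent <- all(vapply(seq_len(k), function(m) {
          others <- vapply(setdiff(seq_len(k), m), function(o)
            dome_value_at(domes[[o]], ctr[m, 1], ctr[m, 2],
                          cfg$ambient_mean_c), 0)
          peaks[m] >= max(others, cfg$ambient_mean_c) + agg$core_excess_c
        }, TRUE))
        if (!prominent) next
        occupied[guard] <- TRUE
        for (m in seq_len(k))
          field <- compose_dome(field, raster, ctr[m, 1], ctr[m, 2],
                                geoms[[m]]$a0, geoms[[m]]$b0, thetas[m],
                                peaks[m], cfg$ambient_mean_c)
        # carve cool seams along the contact lines between member bodies
        if (k > 1L)
          field <- carve_agg_seams(field, raster, domes, cfg$ambient_mean_c,
                                   thr, agg$seam_depression_c,
                                   agg$seam_width_c)
        for (m in seq_len(k)) {
          seal_id <- seal_id + 1L
          seals[[length(seals) + 1L]] <- tibble::tibble(
            id = seal_id, class = agg$member_class, x = ctr[m, 1],
            y = ctr[m, 2], area_m2 = areas[m], body_temp_c = peaks[m],
            agg_id = ai)
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place aggregation ", ai, " after ", max_tries,
             " tries; scene too dense", call. = FALSE)
    }
  }

  raster$values <- field
  seals <- if (length(seals) > 0L) dplyr::bind_rows(seals) else
    tibble::tibble(id = integer(), class = character(), x = numeric(),
                   y = numeric(), area_m2 = numeric(),
                   body_temp_c = numeric(), agg_id = integer())
  points <- tibble::tibble(id = seals$id, x = seals$x, y = seals$y,
                           label = seals$class)
  list(raster = raster,
       truth = list(points = points, seals = seals))
}

# Value of one member's thermal dome at arbitrary world coordinates.
dome_value_at <- function(dome, x, y, base) {
  dx <- x - dome$ctr[1]; dy <- y - dome$ctr[2]
  xr <- dx * cos(dome$theta) + dy * sin(dome$theta)
  yr <- -dx * sin(dome$theta) + dy * cos(dome$theta)
  u2 <- (xr / dome$geom$a0)^2 + (yr / dome$geom$b0)^2
  base + (dome$peak - base) * pmax(1 - u2, 0)
}

smoothstep01 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Subtract Gaussian-profile cool bands along the contact lines between the
# member bodies of one aggregation. The contact between two bodies (the
# crease of the pointwise-maximum composition) is the set where their dome
# values are equal AND no third body is warmer there, so for each pair the
# carve depth falls off with the dome-value difference (width in degC), is
# masked out wherever another member dominates (otherwise a pair's
# equal-value line would trench straight through the body between them),
# and tapers smoothly to zero below the merged zone - every cutoff is
# smooth because a hard edge in the carved field would itself draw a
# spurious high-pass response.
carve_agg_seams <- function(field, raster, domes, base, thr, depth, width_c) {
  if (depth <= 0) return(field)
  k <- length(domes)
  g <- raster$gsd_m
  xs <- vapply(domes, function(d) d$ctr[1], 0)
  ys <- vapply(domes, function(d) d$ctr[2], 0)
  reach <- max(vapply(domes, function(d) d$geom$af, 0)) + 2 * g
  nr <- nrow(field); nc <- ncol(field)
  c1 <- max(1L, floor((min(xs) - reach - raster$xmin) / g)); c2 <- min(nc, ceiling((max(xs) + reach - raster$xmin) / g) + 1L)
  r1 <- max(1L, floor((raster$ymax - max(ys) - reach) / g)); r2 <- min(nr, ceiling((raster$ymax - min(ys) + reach) / g) + 1L)
  if (c1 > c2 || r1 > r2) return(field)
  rows <- r1:r2; cols <- c1:c2
  x <- raster$xmin + (cols - 0.5) * g
  y <- raster$ymax - (rows - 0.5) * g
  gx <- outer(rep(1, length(rows)), x)
  gy <- outer(y, rep(1, length(cols)))
  v <- lapply(domes, function(d) dome_value_at(d, gx, gy, base))
  carve <- matrix(0, length(rows), length(cols))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    touching <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2) <
      0.95 * (domes[[i]]$geom$af + domes[[j]]$geom$af)
    if (!touching) next
    vi <- v[[i]]; vj <- v[[j]]
    pair_max <- pmax(vi, vj)
    others <- setdiff(seq_len(k), c(i, j))
    other_max <- if (length(others) > 0L)
      Reduce(pmax, v[others]) else matrix(base, length(rows), length(cols))
    # the seam widens into a wedge where the bodies approach the footprint
    # rim, so the waist is notched fully open and no rim cell survives
    # past the notch as a spurious one-pixel individual
    w_eff <- width_c *
      (1 + 2 * smoothstep01(((thr + 1.5) - pmax(vi, vj)) / 1.5))
    on_crease <- exp(-((vi - vj) / w_eff)^2)
    merged <- smoothstep01((pmin(vi, vj) - (thr - 2.5)) / 2)
    # keep the carve fully on where the pair ties with a third body (the
    # Y-junction of three members would otherwise get no carve at all) and
    # fade it only once that third body clearly dominates
    top_pair <- smoothstep01((pair_max - other_max + 1.2) / 1.2)
    carve <- pmax(carve, depth * on_crease * merged * top_pair)
  }
  field[rows, cols] <- field[rows, cols] - carve
  field
}

#' Scene configuration for a single multi-seal huddle
#'
#' Canonical study conditions for exercising aggregation splitting: one
#' huddle of `members` seals and nothing else. Members are thin, warm
#' bodies (huddled animals conserve heat, and the shared footprint must
#' stay above the detection threshold across the contact waists) curling
#' along an arc, so the merged polygon is a single thresholded object
#' with one distinct warm core per animal and cool seams between them.
#'
#' @param members Number of seals in the huddle.
#' @param seed Scene seed.
#' @param member_class `"adult"` or `"yoy"`.
#' @param core_spacing_px Spacing between adjacent cores in pixels;
#'   defaults to 11 for adult and 5 for YOY members (proportionate to body
#'   size). The defaults keep huddles compact, which maximises the
#'   reliability of high-pass splitting; larger values (13-15 for adults)
#'   give lankier, more concave outlines that the shape classifier flags
#'   as aggregations more often, at slightly higher risk of the footprint
#'   pinching apart.
#' @param extent_m Scene extent.
#' @return A [scene_config()].
#' @export
huddle_scene_config <- function(members, seed, member_class = "adult",
                                core_spacing_px = NULL,
                                extent_m = c(28, 28)) {
  if (is.null(core_spacing_px))
    core_spacing_px <- if (member_class == "adult") 11 else 5
  scene_config(
    extent_m = extent_m,
    warm_patches = list(count = 0, radius_m = c(0.4, 1.2), excess_c = c(3, 6)),
    yoy = list(count = 0, body_temp_c = c(11, 12.5), area_m2 = c(0.30, 0.55),
               aspect = c(1, 1)),
    adult = list(count = 0, body_temp_c = c(14.5, 16.5), area_m2 = c(0.9, 1.3),
                 aspect = c(1, 1)),
    aggregations = list(count = 1, members = members,
                        member_class = member_class,
                        core_spacing_px = core_spacing_px,
                        core_excess_c = 1.5, seam_depression_c = 2,
                        seam_width_c = 1),
    seed = seed)
}

#' Write ground-truth points
#'
#' Serialises a scene's truth points in the annotation-point format the
#' assessment module reads (`.csv` or `.geojson`).
#'
#' @param truth The `truth` element of [generate_scene()]'s result (or any
#'   list with a `points` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write_points(truth$points, path)
}
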