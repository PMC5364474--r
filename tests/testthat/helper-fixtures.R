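# Shared fixtures and independent oracles for the test suite.

CRS_UTM <- "EPSG:32620"

# small raster from a matrix, defaulting to 8 cm pixels
tr <- function(m, gsd = 0.08, xmin = 0, ymax = nrow(m) * gsd, crs = CRS_UTM) {
  thermal_raster(m, xmin = xmin, ymax = ymax, gsd_m = gsd, crs = crs)
}

# --- independent flood-fill clustering oracle (recursive DFS, unlike the
# --- implementation's iterative stack labelling) -------------------------
flood_fill_oracle <- function(binary, connectivity = 4) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  nbrs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  grow <- function(r, c) {
    out <- list(c(r, c))
    seen[r, c] <<- TRUE
    for (d in nbrs) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          binary[rr, cc] && !seen[rr, cc])
        out <- c(out, grow(rr, cc))
    }
    out
  }
  clusters <- list()
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    if (binary[r, cc] && !seen[r, cc]) {
      cl <- do.call(rbind, grow(r, cc))
      colnames(cl) <- c("row", "col")
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  clusters
}

# canonical form for comparing cluster partitions
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, function(m) {
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    rownames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  keys <- vapply(cl, function(m) paste(m[1, ], collapse = ","), "")
  cl[order(keys)]
}

# --- literal scalar transcription of the classification rule table -------
oracle_label <- function(A, R, Tm, mode, Tstar = 10) {
  if (mode == "complex") {
    if ((A <= 0.85 && Tm < Tstar) || A < 0.65) return("individual_yoy")
    if ((A > 0.65 && A <= 3.5 && R > 0.8 && Tm > Tstar) ||
        (A > 0.85 && A <= 3.5 && R > 0.8)) return("individual_adult")
  } else {
    if (A <= 0.85) return("individual_yoy")
    if (A > 0.85 && A <= 3.5 && R > 0.8) return("individual_adult")
  }
  if ((A > 0.65 && A < 0.85 && R < 0.75) ||
      (A > 0.85 && A < 3.5 && R < 0.8)) return("yoy_aggregation")
  if (A > 3.5 && R < 0.8) return("adult_aggregation")
  "unclassified"
}

# --- brute-force double-loop 3x3 convolution with edge replication -------
brute_force_conv <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), nr)
      c2 <- min(max(cc + dc, 1), nc)
      acc <- acc + kernel[dr + 2, dc + 2] * m[rr, c2]
    }
    out[r, cc] <- acc
  }
  out
}

# detection-tibble row with a square polygon, for assessment tests that
# need no raster
square_det <- function(id, label, x0, y0, side = 1, parent_id = NA_integer_) {
  ring <- cbind(x = c(x0, x0 + side, x0 + side, x0),
                y = c(y0, y0, y0 + side, y0 + side))
  tibble::tibble(id = as.integer(id), pixel_count = NA_integer_,
                 area_m2 = side^2, mean_temp_c = NA_real_,
                 chull_ratio = 1, label = label,
                 parent_id = as.integer(parent_id),
                 geometry = list(list(ring)), cells = list(NULL))
}

pts_tbl <- function(x, y, label, id = seq_along(x)) {
  tibble::tibble(id = as.integer(id), x = x, y = y, label = label)
}

# scene with only isolated seals, small extent, for fast end-to-end tests
small_colony_config <- function(n_yoy, n_adult, seed, extent = c(20, 20), ...) {
  scene_config(
    extent_m = extent,
    yoy = list(count = n_yoy, body_temp_c = c(12, 14),
               area_m2 = c(0.25, 0.60), aspect = c(1.6, 2.6)),
    adult = list(count = n_adult, body_temp_c = c(13, 16),
                 area_m2 = c(1.2, 3.0), aspect = c(1.8, 2.8)),
    seed = seed, ...)
}
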