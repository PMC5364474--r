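# Polygon geometry on pixel clusters.
#
# A polygon is represented as a list of rings; each ring is an n x 2
# numeric matrix of world coordinates (x, y), not closed (first vertex not
# repeated). Ring 1 is the exterior (counter-clockwise, positive shoelace
# area); later rings are holes (clockwise, negative area). This matches
# RFC 7946 winding, so GeoJSON serialisation is direct.

# Signed shoelace area of one ring (n x 2 matrix, open).
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Total polygon area: exterior minus holes.
polygon_area <- function(rings) sum(vapply(rings, ring_signed_area, 0))

#' Trace the boundary of a pixel cluster
#'
#' Converts a set of grid cells into world-coordinate polygon rings: the
#' union of the member pixel squares, with the exterior ring
#' counter-clockwise and any interior holes clockwise. No simplification is
#' applied beyond merging collinear edges, so the traced outline follows
#' pixel edges exactly and its shoelace area equals
#' `pixel_count * gsd^2` minus hole area... i.e. the polygon area always
#' equals `pixel_count * gsd^2`.
#'
#' @param cells Integer matrix with columns `row`, `col` (1-based grid
#'   indices).
#' @param raster The [thermal_raster()] the indices refer to (supplies the
#'   grid-to-world transform).
#' @return A list of rings (n x 2 matrices of x, y).
#' @keywords internal
trace_cluster_rings <- function(cells, raster) {
  stopifnot(nrow(cells) >= 1L)
  g <- raster$gsd_m
  rows <- cells[, 1]; cols <- cells[, 2]
  nrg <- max(rows) + 1L  # local corner grid size (rows 0..max)
  # membership lookup on a cropped window for O(cluster) work
  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  h <- max(rows) - r0 + 2L; w <- max(cols) - c0 + 2L  # pad by 1 cell
  occ <- matrix(FALSE, h, w)
  occ[cbind(rows - r0, cols - c0)] <- TRUE
  inside <- function(r, c) {  # local padded coords
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    out <- logical(length(r)); out[ok] <- occ[cbind(r[ok], c[ok])]
    out
  }
  # Directed boundary edges between corner nodes, interior kept on the left
  # in world (x east, y north) orientation. Corner (i, j) = the corner at
  # row boundary i (0 = top of local row 1), col boundary j.
  lr <- rows - r0; lc <- cols - c0
  from_i <- integer(0); from_j <- integer(0); to_i <- integer(0); to_j <- integer(0)
  add <- function(fi, fj, ti, tj, sel) {
    from_i <<- c(from_i, fi[sel]); from_j <<- c(from_j, fj[sel])
    to_i <<- c(to_i, ti[sel]);     to_j <<- c(to_j, tj[sel])
  }
  top_open    <- !inside(lr - 1L, lc)
  bottom_open <- !inside(lr + 1L, lc)
  left_open   <- !inside(lr, lc - 1L)
  right_open  <- !inside(lr, lc + 1L)
  # top edge: heading west (interior south of edge is on the left)
  add(lr - 1L, lc, lr - 1L, lc - 1L, top_open)
  # bottom edge: heading east
  add(lr, lc - 1L, lr, lc, bottom_open)
  # left edge: heading south (y decreases with i, so left = east = interior)
  add(lr - 1L, lc - 1L, lr, lc - 1L, left_open)
  # right edge: heading north
  add(lr, lc, lr - 1L, lc, right_open)

  nkey <- (w + 1L)
  key <- function(i, j) i * nkey + j + 1L
  fk <- key(from_i, from_j)
  ord <- order(fk)
  fk_s <- fk[ord]
  edge_used <- logical(length(fk))
  # index of first edge per start-node (edges sorted by start key)
  starts <- match(fk_s, fk_s)  # first occurrence index within sorted order

  pick_next <- function(prev_di, prev_dj, cand_idx) {
    # choose the sharpest left turn among candidate outgoing edges
    if (length(cand_idx) == 1L) return(cand_idx)
    best <- cand_idx[1]; best_score <- -Inf
    for (e in cand_idx) {
      di <- to_i[e] - from_i[e]; dj <- to_j[e] - from_j[e]
      # world direction: dx = dj, dy = -di
      cross <- prev_dj * (-di) - (-prev_di) * dj  # prev_dx*dy - prev_dy*dx
      dot <- prev_dj * dj + prev_di * di
      score <- atan2(cross, dot)
      if (score > best_score) { best_score <- score; best <- e }
    }
    best
  }

  rings <- list()
  for (start in seq_along(fk)) {
    if (edge_used[start]) next
    path_i <- from_i[start]; path_j <- from_j[start]
    cur <- start
    repeat {
      edge_used[cur] <- TRUE
      path_i <- c(path_i, to_i[cur]); path_j <- c(path_j, to_j[cur])
      if (to_i[cur] == from_i[start] && to_j[cur] == from_j[start]) break
      k <- key(to_i[cur], to_j[cur])
      cand <- which(fk == k & !edge_used)
      if (length(cand) == 0L) stop("boundary tracing failed (open ring)")
      cur <- pick_next(to_i[cur] - from_i[cur], to_j[cur] - from_j[cur], cand)
    }
    # drop closing vertex, collapse collinear runs
    n <- length(path_i) - 1L
    pi <- path_i[seq_len(n)]; pj <- path_j[seq_len(n)]
    keep <- vapply(seq_len(n), function(t) {
      p <- if (t == 1L) n else t - 1L
      q <- if (t == n) 1L else t + 1L
      d1i <- pi[t] - pi[p]; d1j <- pj[t] - pj[p]
      d2i <- pi[q] - pi[t]; d2j <- pj[q] - pj[t]
      d1i * d2j - d1j * d2i != 0L
    }, TRUE)
    pi <- pi[keep]; pj <- pj[keep]
    x <- raster$xmin + (c0 + pj) * g
    y <- raster$ymax - (r0 + pi) * g
    rings[[length(rings) + 1L]] <- cbind(x = x, y = y)
  }
  # exterior first (largest positive area), holes after
  areas <- vapply(rings, ring_signed_area, 0)
  rings[order(-areas)]
}

#' Convex-hull (solidity) ratio of a polygon
#'
#' The ratio of a polygon's area to the area of its convex hull, in
#' `(0, 1]`. Individual seal bodies threshold to compact, convex-ish
#' outlines with solidity near 1; merged multi-animal aggregations are
#' irregular and score lower. The hull is computed on the exterior ring's
#' vertices; holes reduce polygon area but never the hull.
#'
#' @param rings Polygon rings (list of n x 2 matrices, exterior first) as
#'   produced by the detector.
#' @return A single number in `(0, 1]`.
#' @examples
#' square <- list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' convex_hull_ratio(square)  # 1
#' @export
convex_hull_ratio <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  area <- abs(polygon_area(rings))
  if (area <= 0) stop("polygon has zero area", call. = FALSE)
  pts <- rings[[1]]
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise order
  hull <- pts[rev(h), , drop = FALSE]        # counter-clockwise
  hull_area <- ring_signed_area(hull)
  min(area / hull_area, 1)
}

# Even-odd point-in-polygon over a ring list. boundary = TRUE counts points
# on an edge as inside.
points_in_rings <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  on_boundary <- rep(FALSE, length(x))
  for (ring in rings) {
    res <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
    res_strict <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = FALSE)
    on_boundary <- on_boundary | (res & !res_strict)
    inside <- xor(inside, res_strict)
  }
  inside | on_boundary
}

# Nearest point on the boundary of a polygon (any ring) to (px, py).
# Returns list(x, y, dist).
nearest_on_rings <- function(px, py, rings) {
  best <- list(x = NA_real_, y = NA_real_, dist = Inf)
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    j <- c(2:n, 1L)
    x2 <- x1[j]; y2 <- y1[j]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- ((px - x1) * dx + (py - y1) * dy) / pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    k <- which.min(d2)
    if (sqrt(d2[k]) < best$dist)
      best <- list(x = qx[k], y = qy[k], dist = sqrt(d2[k]))
  }
  best
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
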