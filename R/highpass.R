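# Zero-sum high-pass (edge-enhancement) filtering. A 3x3 neighbourhood
# kernel whose coefficients sum to zero annihilates spatially constant
# temperature and responds positively on local warm peaks and edges,
# negatively in local cool seams - the basis for breaking merged
# multi-animal aggregation polygons into individual seals.

#' High-pass filter kernel
#'
#' Builds a 3x3 zero-sum kernel. The default weights (centre 6.8,
#' edge-adjacent -1.0, corner -0.7) are the standard HIGH filter of common
#' GIS toolchains; alternative coefficients can be supplied as a 3x3 matrix
#' but must sum to zero with a positive centre.
#'
#' @param weights Optional 3x3 numeric matrix of coefficients.
#' @return A 3x3 matrix of class `high_pass_kernel`.
#' @examples
#' high_pass_kernel()
#' @export
high_pass_kernel <- function(weights = NULL) {
  if (is.null(weights)) {
    weights <- matrix(c(-0.7, -1.0, -0.7,
                        -1.0,  6.8, -1.0,
                        -0.7, -1.0, -0.7), 3, 3, byrow = TRUE)
  }
  if (!is.matrix(weights) || !all(dim(weights) == c(3L, 3L)))
    stop("kernel must be a 3x3 matrix", call. = FALSE)
  if (abs(sum(weights)) > 1e-9)
    stop("high-pass kernel coefficients must sum to 0", call. = FALSE)
  if (weights[2, 2] <= 0)
    stop("high-pass kernel centre weight must be positive", call. = FALSE)
  structure(weights, class = c("high_pass_kernel", "matrix", "array"))
}

# Fill NA cells with the value of the nearest valid cell (multi-source
# chebyshev propagation; ties resolved by a fixed direction order, so the
# fill is deterministic). Used so nodata neighbours do not poison the
# convolution.
fill_nearest_valid <- function(v) {
  if (!anyNA(v)) return(v)
  if (all(is.na(v))) stop("raster has no valid cells", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  while (anyNA(v)) {
    filled <- v
    na_mask <- is.na(v)
    for (s in shifts) {
      src <- shift_matrix(v, s[1], s[2])
      take <- na_mask & is.na(filled) & !is.na(src)
      filled[take] <- src[take]
    }
    if (identical(is.na(filled), na_mask)) break  # cannot happen, guard
    v <- filled
  }
  v
}

# shift matrix by (dr, dc), exposing NA at the vacated border
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# shift with edge replication (border cells reuse their nearest in-grid value)
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  cs <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[rs, cs]
}

#' Apply a high-pass filter to a thermal raster
#'
#' Convolves the temperature grid with a 3x3 kernel. Nodata cells are
#' replaced by their nearest valid value before convolution, and cells
#' beyond the grid edge replicate the border, so the response is defined
#' everywhere. For a zero-sum kernel a spatially constant raster yields an
#' all-zero response.
#'
#' @param raster A [thermal_raster()].
#' @param kernel A [high_pass_kernel()].
#' @return A numeric matrix (same shape as the raster) of filter responses.
#' @export
high_pass <- function(raster, kernel = high_pass_kernel()) {
  stopifnot(inherits(raster, "thermal_raster"))
  kernel <- high_pass_kernel(unclass(kernel))
  v <- fill_nearest_valid(raster$values)
  out <- matrix(0, nrow(v), ncol(v))
  for (dr in -1:1) for (dc in -1:1) {
    w <- kernel[dr + 2L, dc + 2L]
    if (w != 0) out <- out + w * shift_replicate(v, -dr, -dc)
  }
  out
}
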