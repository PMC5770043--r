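# Planar geometry primitives. All coordinates are kilometres on a projected
# plane; no geodesy anywhere in the package.

#' Length of a polyline
#'
#' @param coords Numeric matrix with two columns (x, y) in km, one row per
#'   vertex, in drawing order.
#' @return Length in km.
#' @export
polyline_length <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, nrow(coords) >= 2)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param ring Numeric matrix (x, y), open ring (first vertex not repeated).
#' @return Area in km^2 (non-negative).
#' @export
polygon_area <- function(ring) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Geometric centroid of a simple polygon
#'
#' Falls back to the vertex mean when the signed area is numerically zero.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(ring) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cross) / (6 * a), sum((y + y[j]) * cross) / (6 * a))
}

#' Point-in-polygon test (ray casting)
#'
#' Boundary points count as inside.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @inheritParams polygon_area
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xj <- x[c(2:n, 1)]; yj <- y[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- x[k]; y1 <- y[k]; x2 <- xj[k]; y2 <- yj[k]
    # collinear + within bounding box => on the boundary
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_edge <- on_edge | (abs(cr) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Intersection point of two straight segments
#'
#' Returns the intersection of segments p1-p2 and p3-p4 when they cross at a
#' single point (including endpoint touches), or NULL when disjoint, parallel
#' or collinear.
#'
#' @param p1,p2,p3,p4 Numeric length-2 vectors.
#' @return Numeric length-2 vector or NULL.
#' @keywords internal
segment_intersection <- function(p1, p2, p3, p4) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NULL)
  q <- p3 - p1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  eps <- 1e-9
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
  p1 + t * r
}

#' Regular grid of points inside a polygon
#'
#' Used for area-share computations (zone coverage of a village). The grid is
#' deterministic: n x n cell centres over the bounding box, filtered to the
#' polygon interior.
#'
#' @inheritParams polygon_area
#' @param n Points per axis.
#' @return Matrix (x, y) of interior points; at least the centroid when the
#'   grid misses the polygon entirely.
#' @keywords internal
grid_points_in_polygon <- function(ring, n = 12) {
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  gx <- seq(xr[1], xr[2], length.out = n + 1)
  gy <- seq(yr[1], yr[2], length.out = n + 1)
  cx <- (gx[-1] + gx[-(n + 1)]) / 2
  cy <- (gy[-1] + gy[-(n + 1)]) / 2
  pts <- cbind(rep(cx, times = n), rep(cy, each = n))
  keep <- point_in_polygon(pts[, 1], pts[, 2], ring)
  if (!any(keep)) return(matrix(polygon_centroid(ring), ncol = 2))
  pts[keep, , drop = FALSE]
}

# round-half-up at d decimals, as used for every printed rate in the package
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
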