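# Plain planar geometry on polygons given as two-column matrices (x, y).
# Rings need not be closed; all functions close them internally.

#' Polygon area (shoelace formula)
#'
#' @param poly Two-column numeric matrix of vertex coordinates (metres).
#' @return Absolute enclosed area in square units of the input.
#' @keywords internal
poly_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Points exactly on the boundary may fall on either side; callers that need
#' a closed boundary convention should test distance == 0 as well.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column matrix of polygon vertices.
#' @return Logical vector, TRUE where the point lies inside.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman).
# Returns a (possibly empty) two-column matrix.
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1) n else i - 1, ]
      cur_in <- keep(cur); prev_in <- keep(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    # intersection of segment p-q with line coord == val
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- as.matrix(poly)
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  pts
}

# Minimum distance from points (px, py) to the boundary of a polygon ring.
# Vectorised over points; loops over the (few) polygon edges.
dist_to_ring <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    ddx <- px - (x1 + t * dx)
    ddy <- py - (y1 + t * dy)
    d2 <- pmin(d2, ddx * ddx + ddy * ddy)
    j <- i
  }
  sqrt(d2)
}

# Regular polygon approximating a circle; used for water bodies.
circle_polygon <- function(cx, cy, radius, n_vertices = 64L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + radius * cos(theta), cy + radius * sin(theta))
}

rect_polygon <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
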