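# Planar geometry primitives: convex hulls, polygon areas, point-in-polygon,
# segment clipping against discs and convex polygons. All coordinates are
# metres in a single projected CRS.

#' Shoelace area of a simple polygon
#'
#' @param poly two-column matrix of vertices (open ring; the closing edge is
#'   implied).
#' @return area in square metres (always >= 0).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Convex hull of a point set
#'
#' @param x,y coordinate vectors.
#' @return two-column matrix of hull vertices in counter-clockwise order.
#' @export
convex_hull <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  idx <- grDevices::chull(x, y)
  # chull returns clockwise; reverse for counter-clockwise convention
  idx <- rev(idx)
  cbind(x = x[idx], y = y[idx])
}

# TRUE when the three points make a (counter-clockwise) left turn
.cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

#' Point-in-convex-polygon test (closed: boundary counts as inside)
#'
#' @param px,py point coordinates (vectorised).
#' @param poly counter-clockwise convex ring.
#' @param tol slack in metres for the boundary.
#' @return logical vector.
#' @export
point_in_convex <- function(px, py, poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]
    ey <- poly[j, 2] - poly[i, 2]
    cr <- ex * (py - poly[i, 2]) - ey * (px - poly[i, 1])
    inside <- inside & (cr >= -tol * (abs(ex) + abs(ey) + 1))
  }
  inside
}

#' Point-in-polygon for arbitrary simple polygons
#'
#' Thin wrapper over `mgcv::in.out`; boundary behaviour follows that routine
#' (points exactly on the boundary may fall either way at double precision).
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix (open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(px, py))
}

#' Length of a segment clipped to a closed disc
#'
#' Analytic line-circle intersection: the quadratic
#' |A + t(B-A) - C|^2 = r^2 is solved for t and the solution interval is
#' intersected with [0, 1].
#'
#' @param ax,ay,bx,by segment endpoints.
#' @param cx,cy,r disc centre and radius.
#' @return clipped length in metres.
#' @export
segment_length_in_disc <- function(ax, ay, bx, by, cx, cy, r) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(0)
  fx <- ax - cx; fy <- ay - cy
  a <- len2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)       # misses or touches tangentially: length 0
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  lo <- max(t1, 0); hi <- min(t2, 1)
  if (hi <= lo) return(0)
  (hi - lo) * sqrt(len2)
}

#' Total polyline length inside a closed disc
#'
#' @param line two-column vertex matrix of a polyline.
#' @param cx,cy,r disc centre and radius.
#' @return metres of the line inside the disc.
#' @export
polyline_length_in_disc <- function(line, cx, cy, r) {
  line <- as.matrix(line)
  if (nrow(line) < 2) return(0)
  tot <- 0
  for (i in seq_len(nrow(line) - 1L)) {
    tot <- tot + segment_length_in_disc(line[i, 1], line[i, 2],
                                        line[i + 1, 1], line[i + 1, 2],
                                        cx, cy, r)
  }
  tot
}

# orientation-based proper/improper segment intersection (closed segments)
segments_intersect <- function(p1, p2, p3, p4, tol = 1e-12) {
  d1 <- .cross2(p3, p4, p1)
  d2 <- .cross2(p3, p4, p2)
  d3 <- .cross2(p1, p2, p3)
  d4 <- .cross2(p1, p2, p4)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  on_seg <- function(p, q, r) {
    abs(.cross2(p, q, r)) <= tol * (abs(q[1] - p[1]) + abs(q[2] - p[2]) + 1) &&
      r[1] >= min(p[1], q[1]) - tol && r[1] <= max(p[1], q[1]) + tol &&
      r[2] >= min(p[2], q[2]) - tol && r[2] <= max(p[2], q[2]) + tol
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) ||
    on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

#' Does a polyline intersect a convex polygon (closed sets)?
#'
#' A touch at a single vertex counts as intersection.
#'
#' @param line polyline vertex matrix.
#' @param poly convex ring (counter-clockwise).
#' @return logical scalar.
#' @export
polyline_intersects_convex <- function(line, poly) {
  line <- as.matrix(line); poly <- as.matrix(poly)
  if (any(point_in_convex(line[, 1], line[, 2], poly))) return(TRUE)
  n <- nrow(poly)
  for (i in seq_len(nrow(line) - 1L)) {
    p1 <- line[i, ]; p2 <- line[i + 1L, ]
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      if (segments_intersect(p1, p2, poly[j, ], poly[k, ])) return(TRUE)
    }
  }
  FALSE
}
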