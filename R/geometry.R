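# Polygon primitives used throughout the package.
#
# A polygon is an n x 2 numeric matrix of vertices in world micrometers,
# stored as an open ring (the first vertex is not repeated at the end).
# The world frame has its origin at the image top-left, x pointing right
# (columns) and y pointing down (rows).

#' Polygon area (shoelace formula)
#'
#' @param p An n x 2 matrix of vertices (open ring).
#' @return Absolute enclosed area.
#' @export
poly_area <- function(p) abs(poly_signed_area(p))

#' @rdname poly_area
#' @export
poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Polygon perimeter
#' @inheritParams poly_area
#' @export
poly_perimeter <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Polygon centroid (area-weighted; falls back to vertex mean when degenerate)
#' @inheritParams poly_area
#' @export
poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

poly_bbox <- function(p) {
  c(xmin = min(p[, 1]), ymin = min(p[, 2]),
    xmax = max(p[, 1]), ymax = max(p[, 2]))
}

bbox_overlaps <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

# polyclip representation: list of list(x=, y=)
as_pclip <- function(p) list(list(x = p[, 1], y = p[, 2]))

from_pclip <- function(ring) cbind(ring$x, ring$y)

pclip_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, function(r) poly_area(cbind(r$x, r$y)), numeric(1)))
}

#' Intersection area of two polygons
#' @param a,b Polygons (n x 2 matrices).
#' @return The area of their intersection (0 when disjoint).
#' @export
poly_intersection_area <- function(a, b) {
  if (!bbox_overlaps(poly_bbox(a), poly_bbox(b))) return(0)
  pclip_area(polyclip::polyclip(as_pclip(a), as_pclip(b), op = "intersection"))
}

# Union of a list of polygons; returns a list of rings (matrices).
poly_union <- function(polys) {
  acc <- as_pclip(polys[[1]])
  for (p in polys[-1]) {
    acc <- polyclip::polyclip(acc, as_pclip(p), op = "union")
  }
  lapply(acc, from_pclip)
}

#' Repair a polygon ring set to a single simple polygon
#'
#' Self-intersections are resolved (non-zero fill rule) and, when the result
#' is multi-part, only the largest part is kept. Holes are discarded: cells
#' are modelled as simple polygons.
#'
#' @param rings A single polygon matrix or a list of ring matrices.
#' @return A single n x 2 polygon matrix.
#' @export
poly_repair <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  parts <- polyclip::polysimplify(
    lapply(rings, function(r) list(x = r[, 1], y = r[, 2])),
    filltype = "nonzero"
  )
  if (length(parts) == 0L) stop_validation("polygon repair produced empty geometry")
  areas <- vapply(parts, function(r) poly_area(cbind(r$x, r$y)), numeric(1))
  from_pclip(parts[[which.max(areas)]])
}

# Inclusive point-in-polygon test (boundary counts as inside).
points_in_poly <- function(px, py, p) {
  sp::point.in.polygon(px, py, p[, 1], p[, 2]) > 0
}

# Half-open pixel-membership rule: a pixel belongs to a polygon iff its
# center, nudged by +eps in x and y (towards bottom-right), is strictly
# covered. Centers exactly on a left/top boundary therefore count, centers
# on a right/bottom boundary do not.
points_in_poly_halfopen <- function(px, py, p, eps) {
  sp::point.in.polygon(px + eps, py + eps, p[, 1], p[, 2]) > 0
}

# Rasterize a polygon over pixel centers. Pixel (r, c) (0-based) has world
# center (c * pixel_size, r * pixel_size). `rows` and `cols` are 0-based
# pixel index vectors; returns a logical matrix length(rows) x length(cols).
rasterize_polygon <- function(p, rows, cols, pixel_size) {
  eps <- 1e-6 * pixel_size
  g <- expand.grid(y = rows * pixel_size, x = cols * pixel_size)
  inside <- points_in_poly_halfopen(g$x, g$y, p, eps)
  matrix(inside, nrow = length(rows), ncol = length(cols))
}

#' Construct an affine transform
#'
#' @param m A 3 x 3 homogeneous matrix mapping world coordinates of one layer
#'   onto another. Must be invertible.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m))) {
    stop_validation("an affine transform must be a finite 3 x 3 matrix")
  }
  if (abs(det(m)) < 1e-12) {
    stop_validation("affine transform matrix is singular")
  }
  structure(m, class = "affine_transform")
}

#' @rdname affine_transform
#' @param t An `affine_transform`.
#' @export
affine_inverse <- function(t) affine_transform(solve(unclass(t)))

#' Apply an affine transform to points, polygons, transcripts or cells
#'
#' Coordinates are mapped through the homogeneous matrix; geometry is
#' transformed, never resampled.
#'
#' @param x An n x 2 point/vertex matrix, a [transcript_table], or a
#'   [cell_collection].
#' @param t An [affine_transform].
#' @return Object of the same type with transformed coordinates.
#' @export
apply_affine <- function(x, t) {
  if (!inherits(t, "affine_transform")) t <- affine_transform(t)
  UseMethod("apply_affine")
}

#' @export
apply_affine.default <- function(x, t) {
  p <- as.matrix(x)
  h <- cbind(p, 1) %*% t(unclass(t))
  h[, 1:2, drop = FALSE] / h[, 3]
}

#' @export
apply_affine.transcript_table <- function(x, t) {
  xy <- apply_affine.default(cbind(x$x, x$y), t)
  x$x <- xy[, 1]
  x$y <- xy[, 2]
  x
}

#' @export
apply_affine.cell_collection <- function(x, t) {
  x$polygons <- lapply(x$polygons, apply_affine.default, t = t)
  x
}
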