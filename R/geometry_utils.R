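# Small 3D / planar geometry helpers shared by the whisker and spatial
# modules. Angles at the user interface are degrees; internal trigonometry
# is radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 64)
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#'
#' @param axis 3-vector rotation axis (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  k <- unitize(axis)
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# rotate the rows of an n x 3 matrix about an axis through a pivot point
rotate_points <- function(pts, axis, angle_deg, pivot = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, `+`)
}

#' Even-odd point-in-polygon test with boundary counted as inside
#'
#' Ray-casting test for a simple polygon. Points lying exactly on a polygon
#' edge or vertex are counted as inside (the tie-break used throughout the
#' overlap analyses).
#'
#' @param px,py point coordinates (vectorized).
#' @param poly m x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("invalid polygon: fewer than 3 vertices", call. = FALSE)
  m <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:m, 1)]; ye <- ys[c(2:m, 1)]
  n <- length(px)
  inside <- logical(n)
  for (i in seq_len(n)) {
    x <- px[i]; y <- py[i]
    # boundary check: point on any segment?
    dx <- xe - xs; dy <- ye - ys
    cross <- dx * (y - ys) - dy * (x - xs)
    within <- (x - xs) * (x - xe) + (y - ys) * (y - ye) <= 1e-12
    if (any(abs(cross) <= 1e-9 * pmax(abs(dx) + abs(dy), 1) & within)) {
      inside[i] <- TRUE
      next
    }
    crossings <- (ys > y) != (ye > y)
    if (any(crossings)) {
      xint <- xs[crossings] + (y - ys[crossings]) *
        (xe[crossings] - xs[crossings]) / (ye[crossings] - ys[crossings])
      inside[i] <- (sum(xint > x) %% 2L) == 1L
    }
  }
  inside
}

# minimum Euclidean distance from points to a polygon outline
# (0 is NOT returned automatically for interior points: callers combine
# this with point_in_polygon for buffered-membership tests)
dist_to_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  m <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:m, 1)]; ye <- ys[c(2:m, 1)]
  dx <- xe - xs; dy <- ye - ys
  len2 <- dx^2 + dy^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    t <- ((px[i] - xs) * dx + (py[i] - ys) * dy) / pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    qx <- xs + t * dx; qy <- ys + t * dy
    out[i] <- sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }
  out
}

#' Membership in a polygon dilated by a buffer distance
#'
#' A point belongs to the dilated polygon iff it is inside the polygon or
#' within `dilation` of its outline (Euclidean distance in the polygon's
#' coordinate units). For `dilation = 0` this is [point_in_polygon()].
#'
#' @param px,py point coordinates.
#' @param poly m x 2 vertex matrix.
#' @param dilation buffer distance (>= 0).
#' @return logical vector.
#' @export
in_dilated_polygon <- function(px, py, poly, dilation = 0) {
  ins <- point_in_polygon(px, py, poly)
  if (dilation > 0) {
    idx <- which(!ins)
    if (length(idx))
      ins[idx] <- dist_to_polygon(px[idx], py[idx], poly) <= dilation
  }
  ins
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  m <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- x[c(2:m, 1)]; yn <- y[c(2:m, 1)]
  abs(sum(x * yn - xn * y)) / 2
}
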