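#' Visual-space coverage map
#'
#' A simple polygon in eye-centered (azimuth, elevation) degrees describing
#' the part of the visual field represented by VISp, optionally dilated to
#' allow for eye movements (the published allowance is 20 deg in each
#' direction).
#'
#' @param polygon m x 2 matrix or data.frame of vertices
#'   `(azimuth, elevation)` in degrees.
#' @param dilation buffer in degrees applied before point tests (default 0).
#' @return an object of class `"visual_space_map"`.
#' @export
visual_space_map <- function(polygon, dilation = 0) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("visual_space_map: polygon must be an m x 2 matrix, m >= 3",
         call. = FALSE)
  if (dilation < 0) stop("visual_space_map: dilation must be >= 0", call. = FALSE)
  if (any(polygon[, 1] < -30 | polygon[, 1] > 120) ||
      any(polygon[, 2] < -60 | polygon[, 2] > 90))
    stop("visual_space_map: vertices outside the sane angular domain ",
         "(azimuth [-30, 120], elevation [-60, 90])", call. = FALSE)
  if (polygon_self_intersects(polygon))
    stop("visual_space_map: polygon is self-intersecting", call. = FALSE)
  structure(list(polygon = polygon, dilation = dilation),
            class = "visual_space_map")
}

#' @export
print.visual_space_map <- function(x, ...) {
  cat(sprintf("visual-space map: %d vertices, azimuth [%.0f, %.0f], elevation [%.0f, %.0f] deg, dilation %.0f deg\n",
              nrow(x$polygon), min(x$polygon[, 1]), max(x$polygon[, 1]),
              min(x$polygon[, 2]), max(x$polygon[, 2]), x$dilation))
  invisible(x)
}

# segment-pair intersection scan (O(m^2); polygons here are small)
polygon_self_intersects <- function(poly) {
  m <- nrow(poly)
  seg <- cbind(poly, poly[c(2:m, 1), ])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(m - 2)) {
    for (j in seq(i + 2, m)) {
      if (i == 1 && j == m) next # adjacent through closure
      if (inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}
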