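#' Principal axes of a 2D cell cloud
#'
#' PCA of the projected cell positions: `pc1` is the direction of maximal
#' variance, `pc2` the orthogonal direction. Sign convention: each axis is
#' oriented to have a non-negative component along +x (ties broken toward
#' +y), so that repeated runs and mirrored inputs give reproducible axes.
#'
#' @param points2d n x 2 matrix (n >= 2, not all identical).
#' @return list with unit vectors `pc1`, `pc2`, `explained` (variance
#'   fractions, descending, summing to 1) and `center` (column means).
#' @export
pca_axes <- function(points2d) {
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 2) stop("pca_axes: need >= 2 points", call. = FALSE)
  if (all(apply(points2d, 2, function(x) diff(range(x))) < 1e-12))
    stop("pca_axes: degenerate input (all points identical)", call. = FALSE)
  pc <- stats::prcomp(points2d, center = TRUE, scale. = FALSE)
  orient <- function(v) {
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) -v else v
  }
  var <- pc$sdev^2
  list(pc1 = orient(pc$rotation[, 1]), pc2 = orient(pc$rotation[, 2]),
       explained = var / sum(var), center = colMeans(points2d))
}

#' Section a 2D cloud along its principal axes
#'
#' Builds parallel section lines with the slope of `pc2`, spaced exactly
#' `spacing` apart along `pc1` and anchored at the minimum `pc1` score, and
#' assigns every point to a parcel. With `cross = TRUE` a second family of
#' lines along `pc1` is added and parcels become cells of the PC1 x PC2
#' grid. Points exactly on a section line belong to the parcel on the
#' lower-score side.
#'
#' @param points2d n x 2 matrix.
#' @param axes result of [pca_axes()]; computed from `points2d` if omitted.
#' @param spacing distance between adjacent lines in the units of the
#'   coordinates (the published sectioning uses 200 pixels).
#' @param cross also section along the second principal component.
#' @return an object of class `"parcellation"`: list with `axes`,
#'   `spacing`, `cross`, `assignment` (integer parcel id per point),
#'   `parcels` (data.frame: id, bin1, bin2, n, fraction),
#'   `section_lines` (data.frame: family, k, slope, intercept, point_x,
#'   point_y, dir_x, dir_y; slope/intercept are NA for vertical lines --
#'   use the parametric point+direction form), and `score_range`.
#' @export
parcellate <- function(points2d, axes = NULL, spacing = 200, cross = FALSE) {
  points2d <- as.matrix(points2d)
  if (spacing <= 0) stop("parcellate: spacing must be > 0", call. = FALSE)
  if (is.null(axes)) axes <- pca_axes(points2d)
  ctr <- sweep(points2d, 2, axes$center)
  s1 <- drop(ctr %*% axes$pc1)
  s2 <- drop(ctr %*% axes$pc2)

  bin_of <- function(s) {
    d <- s - min(s)
    b <- ceiling(d / spacing - 1e-9) # lower-side boundary rule
    b[d <= 1e-9] <- 0L
    as.integer(b)
  }
  b1 <- bin_of(s1)
  b2 <- if (cross) bin_of(s2) else rep(0L, length(s2))

  key <- paste(b1, b2, sep = ":")
  uk <- sort(unique(key))
  assignment <- match(key, uk)
  tab <- table(factor(key, levels = uk))
  bb <- do.call(rbind, strsplit(uk, ":"))
  parcels <- data.frame(id = seq_along(uk),
                        bin1 = as.integer(bb[, 1]), bin2 = as.integer(bb[, 2]),
                        n = as.integer(tab),
                        fraction = as.integer(tab) / length(b1))

  lines_for <- function(score, along, family) {
    # one line per boundary that separates adjacent non-degenerate parcels:
    # the anchor line through the minimum score plus every spacing multiple
    # strictly below the maximum score
    nl <- ceiling((max(score) - min(score)) / spacing - 1e-9)
    if (nl < 1) return(NULL)
    ks <- 0:(nl - 1L)
    anchor_axis <- if (family == 1L) axes$pc1 else axes$pc2
    dir <- if (family == 1L) axes$pc2 else axes$pc1
    pts <- t(vapply(ks, function(k) {
      axes$center + (min(score) + k * spacing) * anchor_axis
    }, numeric(2)))
    dir <- unname(dir)
    slope <- if (abs(dir[1]) < 1e-12) NA_real_ else dir[2] / dir[1]
    intercept <- if (is.na(slope)) NA_real_ else pts[, 2] - slope * pts[, 1]
    data.frame(family = family, k = ks, slope = slope, intercept = intercept,
               point_x = unname(pts[, 1]), point_y = unname(pts[, 2]),
               dir_x = dir[1], dir_y = dir[2])
  }
  section_lines <- lines_for(s1, axes$pc1, 1L)
  if (cross) section_lines <- rbind(section_lines, lines_for(s2, axes$pc2, 2L))

  structure(list(axes = axes, spacing = spacing, cross = cross,
                 assignment = assignment, parcels = parcels,
                 section_lines = section_lines,
                 score_range = list(s1 = range(s1), s2 = range(s2))),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels (%s grid, spacing %g)\n",
              nrow(x$parcels), if (x$cross) "PC1 x PC2" else "PC1", x$spacing))
  invisible(x)
}

#' Smoothed 2D cell-density map
#'
#' Gaussian kernel density estimate with the full data covariance and
#' Scott's bandwidth factor `n^(-1/6)`, evaluated on a uniform grid at the
#' given step over the data limits padded by `pad_bandwidths` marginal
#' bandwidths per side (padding relaxes edge effects for the contours and
#' is cut off afterwards).
#'
#' @param points2d n x 2 matrix (n >= 2).
#' @param grid_step grid step in coordinate units (the published maps use
#'   58, i.e. ~200/sqrt(12), pixels).
#' @param pad_bandwidths padding per side, in marginal bandwidths.
#' @return an object of class `"density_map"`: list with trimmed grid
#'   vectors `x`, `y` and matrix `z` (density, x indexing rows), the padded
#'   `x_pad`, `y_pad`, `z_pad`, the `argmax` (c(x, y) of the maximum on the
#'   trimmed grid), `bandwidth` (2x2 matrix), and `contours`
#'   (grDevices::contourLines output at automatically chosen levels).
#' @export
density_map <- function(points2d, grid_step = 58, pad_bandwidths = 3) {
  points2d <- as.matrix(points2d)
  n <- nrow(points2d)
  if (n < 2) stop("density_map: need >= 2 points", call. = FALSE)
  S <- stats::cov(points2d)
  if (!all(is.finite(S)) || det(S) <= 1e-12 * max(diag(S), 1)^2) {
    warning("density_map: singular covariance; jittering input", call. = FALSE)
    points2d <- points2d +
      matrix(stats::rnorm(2 * n, 0, max(grid_step, 1) * 1e-3), n, 2)
    S <- stats::cov(points2d)
  }
  H <- S * n^(-1 / 3) # Scott: factor n^(-1/6) on the scale of sd
  pad <- pad_bandwidths * sqrt(diag(H))
  lim <- apply(points2d, 2, range)
  # grid laid out symmetrically around the data midpoint so that mirror
  # symmetries of the input are reflected exactly in the evaluated field
  sym_grid <- function(r, p) {
    mid <- mean(r)
    k <- ceiling((diff(r) / 2 + p) / grid_step)
    mid + (-k:k) * grid_step
  }
  gx <- sym_grid(lim[, 1], pad[1])
  gy <- sym_grid(lim[, 2], pad[2])

  Hc <- chol(H)
  # whiten both grid points and data, then sum standard-normal kernels
  white <- function(m) t(backsolve(Hc, t(m), transpose = TRUE))
  wd <- white(points2d)
  gpts <- as.matrix(expand.grid(x = gx, y = gy))
  wg <- white(gpts)
  norm_const <- 1 / (2 * pi * prod(diag(Hc)) * n)
  d1 <- outer(wg[, 1], wd[, 1], `-`)
  d2 <- outer(wg[, 2], wd[, 2], `-`)
  z <- norm_const * rowSums(exp(-0.5 * (d1 * d1 + d2 * d2)))
  zm <- matrix(z, nrow = length(gx), ncol = length(gy))

  keep_x <- gx >= lim[1, 1] & gx <= lim[2, 1]
  keep_y <- gy >= lim[1, 2] & gy <= lim[2, 2]
  zt <- zm[keep_x, keep_y, drop = FALSE]
  am <- arrayInd(which.max(zt), dim(zt))
  contours <- grDevices::contourLines(gx, gy, zm)

  structure(list(x = gx[keep_x], y = gy[keep_y], z = zt,
                 x_pad = gx, y_pad = gy, z_pad = zm,
                 argmax = c(x = gx[keep_x][am[1]], y = gy[keep_y][am[2]]),
                 bandwidth = H, grid_step = grid_step, contours = contours),
            class = "density_map")
}

#' Barrel map container
#'
#' @param raster 2D integer matrix: 0 = background/septa, `b` > 0 = barrel
#'   id. Row index maps to x, column index to y (pixel centers at integer
#'   coordinates minus 0.5).
#' @param pixel_area area per pixel (default 1).
#' @return an object of class `"barrel_map"`.
#' @export
barrel_map <- function(raster, pixel_area = 1) {
  raster <- as.matrix(raster)
  storage.mode(raster) <- "integer"
  if (any(raster < 0)) stop("barrel_map: labels must be non-negative", call. = FALSE)
  if (max(raster) < 1) stop("barrel_map: at least one barrel required", call. = FALSE)
  structure(list(raster = raster, pixel_area = pixel_area),
            class = "barrel_map")
}

# label of the pixel containing each point; 0 outside the raster
# (linear indexing: this is the hot path of the permutation null)
lookup_labels <- function(map, x, y) {
  nr <- nrow(map$raster); nc <- ncol(map$raster)
  i <- floor(x); j <- floor(y)
  ok <- i >= 0 & i < nr & j >= 0 & j < nc
  lab <- integer(length(x))
  lab[ok] <- map$raster[i[ok] + j[ok] * nr + 1]
  lab
}

barrel_areas <- function(map) {
  ids <- sort(unique(as.vector(map$raster)))
  ids <- ids[ids > 0]
  tab <- tabulate(as.vector(map$raster), nbins = max(ids))
  stats::setNames(tab[ids], ids)
}

#' Area-normalized relative fraction index per barrel
#'
#' For each barrel `b` and layer,
#' `fr_b = (#Cells_b / #Cells_tot) * (#Area_tot / #Area_b)`,
#' where `#Cells_tot` is the total number of cells over all layers supplied
#' (the shared denominator puts the layers on the same scale), `#Area_b`
#' the pixel count of barrel `b` and `#Area_tot` the pixel count of the
#' whole depicted barrel field (the full raster, septa included). Cells
#' outside every barrel contribute to `#Cells_tot` only.
#'
#' @param cells data.frame with columns `x`, `y` and `layer`.
#' @param map a [barrel_map()].
#' @return matrix of `fr` values, barrels in rows (names = barrel ids),
#'   layers in columns; attribute `counts` holds the raw per-barrel counts.
#' @export
barrel_fraction_index <- function(cells, map) {
  stopifnot(inherits(map, "barrel_map"))
  if (nrow(cells) < 1) stop("barrel_fraction_index: no cells", call. = FALSE)
  areas <- barrel_areas(map)
  if (any(areas == 0)) stop("barrel with zero area", call. = FALSE)
  area_tot <- length(map$raster)
  layers <- sort(unique(as.character(cells$layer)))
  n_tot <- nrow(cells)
  lab <- lookup_labels(map, cells$x, cells$y)
  ids <- as.integer(names(areas))
  counts <- sapply(layers, function(ly) {
    l <- lab[cells$layer == ly]
    vapply(ids, function(b) sum(l == b), integer(1))
  })
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(names(areas), layers))
  fr <- sweep(counts / n_tot, 1, area_tot / areas, `*`)
  attr(fr, "counts") <- counts
  fr
}

#' One-tailed permutation test for barrel-wise cell enrichment
#'
#' Tests, per barrel and layer, whether the observed relative fraction
#' index `fr_b` exceeds chance. The null is built by uniformly repositioning
#' all of a layer's cells over the barrel-field support `n_shuffles` times
#' and recomputing `fr_b` each time; the empirical one-tailed p-value uses
#' the add-one rule `p = (1 + #\{fr_sh >= fr_obs\}) / (1 + n_shuffles)`, so
#' p is never 0. With `correction = "max-stat"` the null statistic is the
#' per-shuffle maximum over barrels, giving family-wise control; the
#' default applies the strict published per-barrel alpha (0.001) as the
#' multiplicity guard.
#'
#' @param cells data.frame with `x`, `y`, `layer`.
#' @param map a [barrel_map()].
#' @param n_shuffles number of shuffles (>= 100; default 2500).
#' @param alpha significance level (default 0.001).
#' @param seed RNG seed (mandatory).
#' @param support `"bbox"` (default): shuffle uniformly over the whole
#'   rectangular raster extent including septa; `"barrels"`: uniformly over
#'   barrel pixels only.
#' @param correction `"per-barrel"` (default) or `"max-stat"`.
#' @return an object of class `"permutation_result"`: list with `fr_obs`
#'   (barrels x layers), `p` (same shape), `significant`, `null` (list per
#'   layer: n_shuffles x barrels matrix), `alpha`, `n_shuffles`, `seed`.
#' @export
barrel_permutation_test <- function(cells, map, n_shuffles = 2500,
                                    alpha = 0.001, seed,
                                    support = c("bbox", "barrels"),
                                    correction = c("per-barrel", "max-stat")) {
  stopifnot(inherits(map, "barrel_map"))
  support <- match.arg(support)
  correction <- match.arg(correction)
  if (missing(seed)) stop("barrel_permutation_test: seed is mandatory", call. = FALSE)
  if (n_shuffles < 100) stop("n_shuffles must be >= 100", call. = FALSE)
  if (nrow(cells) < 1) stop("no cells", call. = FALSE)

  fr_obs <- barrel_fraction_index(cells, map)
  areas <- barrel_areas(map)
  nb <- length(areas)
  area_tot <- length(map$raster)
  n_tot <- nrow(cells)
  layers <- colnames(fr_obs)
  nr <- nrow(map$raster); nc <- ncol(map$raster)

  barrel_pix <- NULL
  if (support == "barrels") barrel_pix <- which(map$raster > 0)

  set.seed(as.integer(seed %% .Machine$integer.max))
  null <- list(); p <- fr_obs * NA
  for (ly in layers) {
    n_ly <- sum(cells$layer == ly)
    if (support == "bbox") {
      xs <- stats::runif(n_ly * n_shuffles, 0, nr)
      ys <- stats::runif(n_ly * n_shuffles, 0, nc)
      lab <- lookup_labels(map, xs, ys)
    } else {
      pix <- sample(barrel_pix, n_ly * n_shuffles, replace = TRUE)
      lab <- as.vector(map$raster)[pix]
    }
    shuffle_id <- rep(seq_len(n_shuffles), each = n_ly)
    keep <- lab > 0
    cnt <- matrix(tabulate(lab[keep] + nb * (shuffle_id[keep] - 1L),
                           nbins = nb * n_shuffles),
                  nrow = nb)
    fr_sh <- (cnt / n_tot) * (area_tot / areas) # recycles areas down columns
    null[[ly]] <- t(fr_sh)
    if (correction == "per-barrel") {
      p[, ly] <- (1 + rowSums(fr_sh >= fr_obs[, ly])) / (1 + n_shuffles)
    } else {
      mx <- apply(fr_sh, 2, max)
      p[, ly] <- vapply(fr_obs[, ly],
                        function(o) (1 + sum(mx >= o)) / (1 + n_shuffles),
                        numeric(1))
    }
  }
  structure(list(fr_obs = fr_obs, p = p, significant = p < alpha,
                 null = null, alpha = alpha, n_shuffles = n_shuffles,
                 seed = seed, support = support, correction = correction),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  ns <- colSums(x$significant)
  cat(sprintf("barrel permutation test: %d barrels, %d shuffles, alpha %g (%s)\n",
              nrow(x$fr_obs), x$n_shuffles, x$alpha, x$correction))
  for (ly in colnames(x$fr_obs))
    cat(sprintf("  layer %s: %d significant barrel(s)\n", ly, ns[[ly]]))
  invisible(x)
}

#' Assign visual-space coordinates to parcels
#'
#' Maps every parcel of a [parcellate()] result through a retinotopy (a
#' mapping from cortical (x, y) to visual-field (azimuth, elevation)) and
#' weights each resulting visual-space patch by the parcel's cell fraction.
#' Parcels whose fraction reaches `threshold` form the merged coverage
#' region, returned as the list of selected patches together with a
#' membership predicate (union of patch preimages).
#'
#' @param parcellation a `"parcellation"` object.
#' @param retinotopy a [gen_retinotopy()] object, or any function mapping
#'   an n x 2 matrix to an n x 2 matrix of (azimuth, elevation).
#' @param threshold fraction threshold for the merged region (default 0.05).
#' @param vertices_per_edge sampling density of parcel outlines before
#'   mapping (higher follows a curved retinotopy more closely).
#' @return list with `patches` (per parcel: id, fraction, polygon in visual
#'   space), `selected` (parcel ids with fraction >= threshold),
#'   `in_merged` (function(az, el) -> logical: membership in the union of
#'   selected patches, evaluated through the cortical-side parcel test),
#'   and `excluded` (parcel ids outside the retinotopy domain, if any).
#' @export
parcel_visual_coverage <- function(parcellation, retinotopy, threshold = 0.05,
                                   vertices_per_edge = 8L) {
  stopifnot(inherits(parcellation, "parcellation"))
  fun <- if (is.function(retinotopy)) retinotopy else retinotopy$fun
  domain <- if (is.function(retinotopy)) NULL else retinotopy$domain

  axes <- parcellation$axes
  sp <- parcellation$spacing
  r1 <- parcellation$score_range$s1
  r2 <- parcellation$score_range$s2

  bounds1 <- function(b) {
    # bin b collects scores in (min + (b-1)*sp, min + b*sp]; bin 0 is the
    # anchor point itself
    lo <- r1[1] + max(b - 1, 0) * sp
    hi <- min(r1[1] + b * sp, r1[2])
    c(lo, min(lo + if (b == 0) 0 else sp, hi))
  }
  bounds2 <- function(b) {
    lo <- r2[1] + max(b - 1, 0) * sp
    hi <- min(r2[1] + b * sp, r2[2])
    if (!parcellation$cross) return(r2)
    c(lo, min(lo + if (b == 0) 0 else sp, hi))
  }

  mk_poly <- function(b1, b2) {
    u <- bounds1(b1); v <- bounds2(b2)
    if (diff(u) <= 0) u <- u + c(-sp * 1e-3, sp * 1e-3)
    if (diff(v) <= 0) v <- v + c(-sp * 1e-3, sp * 1e-3)
    tt <- seq(0, 1, length.out = vertices_per_edge)
    edge <- function(p, q) cbind(p[1] + tt * (q[1] - p[1]),
                                 p[2] + tt * (q[2] - p[2]))
    corners <- rbind(c(u[1], v[1]), c(u[2], v[1]), c(u[2], v[2]), c(u[1], v[2]))
    ring <- rbind(edge(corners[1, ], corners[2, ])[-vertices_per_edge, ],
                  edge(corners[2, ], corners[3, ])[-vertices_per_edge, ],
                  edge(corners[3, ], corners[4, ])[-vertices_per_edge, ],
                  edge(corners[4, ], corners[1, ])[-vertices_per_edge, ])
    # scores -> cortical coordinates
    sweep(ring %*% rbind(axes$pc1, axes$pc2), 2, axes$center, `+`)
  }

  patches <- list(); excluded <- integer(0)
  for (i in seq_len(nrow(parcellation$parcels))) {
    pr <- parcellation$parcels[i, ]
    ring <- mk_poly(pr$bin1, pr$bin2)
    if (!is.null(domain)) {
      out <- ring[, 1] < domain$x[1] | ring[, 1] > domain$x[2] |
        ring[, 2] < domain$y[1] | ring[, 2] > domain$y[2]
      if (any(out)) {
        warning("parcel ", pr$id, " outside retinotopy domain; excluded",
                call. = FALSE)
        excluded <- c(excluded, pr$id)
        next
      }
    }
    patches[[length(patches) + 1L]] <-
      list(id = pr$id, fraction = pr$fraction,
           cortical = ring, polygon = fun(ring))
  }

  fracs <- vapply(patches, function(p) p$fraction, numeric(1))
  selected <- vapply(patches, function(p) p$id, integer(1))[fracs >= threshold]
  sel_patches <- Filter(function(p) p$id %in% selected, patches)

  in_merged <- function(az, el) {
    if (!length(sel_patches)) return(rep(FALSE, length(az)))
    ins <- rep(FALSE, length(az))
    for (p in sel_patches)
      ins <- ins | point_in_polygon(az, el, p$polygon)
    ins
  }
  list(patches = patches, selected = selected, in_merged = in_merged,
       excluded = excluded, threshold = threshold)
}
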