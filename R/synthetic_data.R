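# Seeded generators for every input the pipeline consumes. Each generator
# draws from its own RNG stream, derived from the master seed by stable
# hashing of the block name, so adding randomness to one block never
# perturbs another. All latent ground truth is recorded in a `truth`
# attribute/sidecar for recovery tests.

block_seed <- function(seed, block) {
  h <- sum(utf8ToInt(block) * seq_along(utf8ToInt(block)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_block_seed <- function(seed, block, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(block_seed(seed, block))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the seed with per-block parameter lists. Defaults emulate the
#' study's inputs: a 24-whisker mouse array (rows A-E plus the greek
#' column, arcs 1-4, caudal whiskers longest), a VISp visual-field polygon
#' covering 0-90 deg azimuth and roughly -25 to +60 deg elevation,
#' anisotropic cell clouds with a known variance split, a grid of
#' elliptical barrel columns with controllable per-barrel enrichment, and
#' an affine or smooth retinotopy. Units: mm for whisker geometry, abstract
#' atlas pixels for clouds and rasters, degrees for angular data.
#'
#' @param seed master seed (mandatory).
#' @param whisker,space,cloud,barrel,retinotopy named lists merged over the
#'   block defaults (see the generator documentation for the fields).
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(seed, whisker = list(), space = list(),
                             cloud = list(), barrel = list(),
                             retinotopy = list()) {
  if (missing(seed)) stop("generator_config: seed is mandatory", call. = FALSE)
  defaults <- list(
    whisker = list(
      # arc-length schedule (mm), caudal-most (greek) longest
      length_by_arc = c(greek = 28, `1` = 24, `2` = 19, `3` = 14, `4` = 9),
      length_jitter = 0.04,        # relative sd
      curvature = 0.025,           # 1/mm
      curvature_jitter = 0.25,     # relative sd
      # emergence azimuth: caudal whiskers point caudally at rest
      theta_by_arc = c(greek = 112, `1` = 103, `2` = 94, `3` = 85, `4` = 76),
      phi_by_row = c(A = 24, B = 12, C = 0, D = -12, E = -24),
      angle_jitter = 2.5,          # deg sd on phi and theta
      zeta_sd = 8,                 # deg sd around ventral (0)
      pad_x = c(greek = 11, `1` = 12.5, `2` = 14, `3` = 15.5, `4` = 17),
      pad_y = 6.2, pad_bulge = 0.05,
      row_z = c(A = 2.5, B = 1.25, C = 0, D = -1.25, E = -2.5),
      greek_z_drop = 0.6,
      eye = c(6, 4.5, 3.5),
      n_points = 50L),
    space = list(
      azimuth_range = c(0, 90), elevation_range = c(-25, 60),
      n_boundary = 6L, dilation = 0),
    cloud = list(
      n = 2000L, center = c(500, 500), axis_deg = 30,
      total_var = 2 * 90^2, split = c(0.8, 0.2),
      z_sd = 20, layers = c("L2/3", "L6"), layer_prob = c(0.5, 0.5),
      n_animals = 5L),
    barrel = list(
      width = 400L, height = 400L, n_rows = 5L, n_cols = 4L,
      rx = 16, ry = 13, margin = 45,
      enrichment = NULL,           # named per-barrel factors, default all 1
      n_cells = 2000L, layer_split = c(0.5, 0.5)),
    retinotopy = list(
      type = "affine",             # "identity", "affine", "smooth"
      domain = list(x = c(0, 1000), y = c(0, 1000)),
      azimuth_range = c(0, 90), elevation_range = c(-25, 60),
      warp = 0.08))
  merge <- function(d, o) { d[names(o)] <- o; d }
  structure(list(seed = seed,
                 whisker = merge(defaults$whisker, whisker),
                 space = merge(defaults$space, space),
                 cloud = merge(defaults$cloud, cloud),
                 barrel = merge(defaults$barrel, barrel),
                 retinotopy = merge(defaults$retinotopy, retinotopy)),
            class = "generator_config")
}

#' Generate a synthetic whisker array
#'
#' Places 24 whiskers (rows A-E x arcs 1-4 plus greek alpha-delta) on a
#' parametric mystacial pad on the left snout, with arc-length and
#' emergence-angle schedules plus seeded jitter. Caudal whiskers (greek,
#' arc 1) are the longest; basepoints lie on the pad surface; the left eye
#' sits dorso-caudal to the pad.
#'
#' @param config a [generator_config()].
#' @return a [whisker_array()] with a `truth` attribute recording the
#'   schedules actually drawn.
#' @export
gen_whisker_array <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cw <- config$whisker
  with_block_seed(config$seed, "whisker", {
    rows <- c("A", "B", "C", "D", "E")
    greeks <- c("alpha", "beta", "gamma", "delta")
    specs <- list()
    for (rw in rows) for (ac in 1:4)
      specs[[length(specs) + 1L]] <- list(row = rw, arc = ac,
                                          arc_key = as.character(ac))
    for (g in seq_along(greeks))
      specs[[length(specs) + 1L]] <- list(row = "greek", arc = greeks[g],
                                          arc_key = "greek",
                                          host_row = rows[g])
    ws <- lapply(specs, function(sp) {
      host <- if (is.null(sp$host_row)) sp$row else sp$host_row
      x <- cw$pad_x[[sp$arc_key]]
      z <- cw$row_z[[host]] - if (sp$arc_key == "greek") cw$greek_z_drop else 0
      y <- cw$pad_y - cw$pad_bulge * ((x - 14)^2 / 4 + z^2 / 4)
      L <- cw$length_by_arc[[sp$arc_key]] *
        exp(stats::rnorm(1, 0, cw$length_jitter))
      whisker(sp$row, sp$arc,
              basepoint = c(x, y, z),
              phi_w = cw$phi_by_row[[host]] + stats::rnorm(1, 0, cw$angle_jitter),
              theta_w = cw$theta_by_arc[[sp$arc_key]] +
                stats::rnorm(1, 0, cw$angle_jitter),
              zeta_w = stats::rnorm(1, 0, cw$zeta_sd),
              length = L,
              curvature = cw$curvature *
                exp(stats::rnorm(1, 0, cw$curvature_jitter)),
              n_points = cw$n_points)
    })
    arr <- whisker_array(ws, eye = cw$eye)
    attr(arr, "truth") <- list(length_by_arc = cw$length_by_arc,
                               eye = cw$eye, seed = config$seed)
    arr
  })
}

#' Generate the VISp visual-space polygon
#'
#' A simple polygon covering the configured azimuth/elevation box with a
#' gently rounded temporal boundary (deterministic template; no sampling).
#'
#' @param config a [generator_config()].
#' @param dilation optional dilation (deg) stored in the map.
#' @return a [visual_space_map()].
#' @export
gen_visual_space <- function(config, dilation = config$space$dilation) {
  cs <- config$space
  az <- cs$azimuth_range; el <- cs$elevation_range
  k <- cs$n_boundary
  # lower edge nasal->temporal, rounded high-azimuth corner, upper edge back
  t <- seq(0, 1, length.out = k)
  lower <- cbind(az[1] + t * diff(az), el[1] + 3 * sin(pi * t))
  right <- cbind(az[2] - 4 * (1 - cos(pi * t)) / 2, el[1] + t * diff(el))
  upper <- cbind(rev(az[1] + t * diff(az)), el[2] - 3 * sin(pi * rev(t)))
  poly <- rbind(lower[-k, ], right[-k, ], upper[-k, ], c(az[1], el[1] + 1))
  visual_space_map(poly, dilation = dilation)
}

#' Generate an anisotropic 3D cell cloud
#'
#' Samples a Gaussian cloud in the xy-plane with principal axis at
#' `axis_deg` and the configured variance split, small-variance z, random
#' layer and animal labels. The latent axis, split and density peak are
#' recorded for recovery tests.
#'
#' @param config a [generator_config()].
#' @return data.frame (`x`, `y`, `z`, `layer`, `animal`) of class
#'   `c("cell_cloud", "data.frame")` with attributes `truth` and
#'   `projection_axes = c("x", "y")`.
#' @export
gen_cell_cloud <- function(config) {
  cc <- config$cloud
  with_block_seed(config$seed, "cloud", {
    n <- cc$n
    a <- deg2rad(cc$axis_deg)
    u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
    sd1 <- sqrt(cc$total_var * cc$split[1])
    sd2 <- sqrt(cc$total_var * cc$split[2])
    s1 <- stats::rnorm(n, 0, sd1); s2 <- stats::rnorm(n, 0, sd2)
    xy <- cbind(cc$center[1] + s1 * u[1] + s2 * v[1],
                cc$center[2] + s1 * u[2] + s2 * v[2])
    out <- data.frame(
      x = xy[, 1], y = xy[, 2],
      z = stats::rnorm(n, 0, cc$z_sd),
      layer = sample(cc$layers, n, replace = TRUE, prob = cc$layer_prob),
      animal = sample(seq_len(cc$n_animals), n, replace = TRUE))
    attr(out, "projection_axes") <- c("x", "y")
    attr(out, "truth") <- list(axis_deg = cc$axis_deg, split = cc$split,
                               peak = cc$center, seed = config$seed)
    class(out) <- c("cell_cloud", "data.frame")
    out
  })
}

#' Generate a barrel-column label raster and an enriched cell cloud
#'
#' Lays out `n_rows` x `n_cols` elliptical barrels on a rectangular field
#' (0 = septa/background) and samples cells from a density that is uniform
#' over the field except inside enriched barrels, where it is multiplied by
#' the per-barrel enrichment factor (factor 1 everywhere reproduces the
#' uniform null).
#'
#' @param config a [generator_config()].
#' @return list with `map` (a [barrel_map()]), `cells` (data.frame `x`,
#'   `y`, `layer`) and `truth` (enrichment factors, barrel centers).
#' @export
gen_barrel_map <- function(config) {
  cb <- config$barrel
  with_block_seed(config$seed, "barrel", {
    nb <- cb$n_rows * cb$n_cols
    cx <- seq(cb$margin, cb$width - cb$margin, length.out = cb$n_rows)
    cy <- seq(cb$margin, cb$height - cb$margin, length.out = cb$n_cols)
    centers <- as.matrix(expand.grid(x = cx, y = cy))
    raster <- matrix(0L, cb$width, cb$height)
    px <- rep(seq_len(cb$width) - 0.5, times = cb$height)
    py <- rep(seq_len(cb$height) - 0.5, each = cb$width)
    for (b in seq_len(nb)) {
      inside <- ((px - centers[b, 1]) / cb$rx)^2 +
        ((py - centers[b, 2]) / cb$ry)^2 <= 1
      raster[inside] <- b
    }
    map <- barrel_map(raster)

    enr <- rep(1, nb)
    if (!is.null(cb$enrichment)) {
      idx <- as.integer(names(cb$enrichment))
      enr[idx] <- as.numeric(cb$enrichment)
    }
    # sampling density f(x) proportional to enr[b] inside barrel b, 1 outside
    areas <- barrel_areas(map)
    w_bg <- length(raster) - sum(areas)
    w <- c(w_bg, areas * enr)
    comp <- sample.int(nb + 1L, cb$n_cells, replace = TRUE, prob = w) - 1L
    xs <- numeric(cb$n_cells); ys <- numeric(cb$n_cells)
    for (i in seq_len(cb$n_cells)) {
      repeat {
        if (comp[i] == 0L) {
          x <- stats::runif(1, 0, cb$width); y <- stats::runif(1, 0, cb$height)
          if (lookup_labels(map, x, y) == 0L) break
        } else {
          b <- comp[i]
          x <- centers[b, 1] + stats::runif(1, -cb$rx, cb$rx)
          y <- centers[b, 2] + stats::runif(1, -cb$ry, cb$ry)
          if (lookup_labels(map, x, y) == b) break
        }
      }
      xs[i] <- x; ys[i] <- y
    }
    layer <- sample(c("L2/3", "L6"), cb$n_cells, replace = TRUE,
                    prob = cb$layer_split)
    list(map = map,
         cells = data.frame(x = xs, y = ys, layer = layer),
         truth = list(enrichment = enr, centers = centers,
                      seed = config$seed))
  })
}

#' Generate a retinotopy mapping
#'
#' Returns a mapping from cortical (x, y) to visual-field (azimuth,
#' elevation) degrees over a rectangular domain. Types: `"identity"`
#' (coordinates pass through), `"affine"` (linear ramps spanning the
#' configured ranges), `"smooth"` (affine plus a small sinusoidal warp with
#' everywhere-positive Jacobian, hence invertible on the domain).
#'
#' @param config a [generator_config()].
#' @return an object of class `"retinotopy"`: list with `fun`
#'   (n x 2 matrix -> n x 2 matrix), `type`, `domain`, and `jacobian`
#'   (function returning the determinant at given points).
#' @export
gen_retinotopy <- function(config) {
  cr <- config$retinotopy
  dom <- cr$domain
  azr <- cr$azimuth_range; elr <- cr$elevation_range
  ax <- diff(azr) / diff(dom$x); ex <- diff(elr) / diff(dom$y)
  base <- function(m) {
    m <- matrix(as.numeric(m), ncol = 2)
    cbind(azr[1] + (m[, 1] - dom$x[1]) * ax,
          elr[1] + (m[, 2] - dom$y[1]) * ex)
  }
  if (cr$type == "identity") {
    fun <- function(m) matrix(as.numeric(m), ncol = 2)
    jac <- function(m) rep(1, nrow(matrix(as.numeric(m), ncol = 2)))
  } else if (cr$type == "affine") {
    fun <- base
    jac <- function(m) rep(ax * ex, nrow(matrix(as.numeric(m), ncol = 2)))
  } else if (cr$type == "smooth") {
    w <- cr$warp
    fun <- function(m) {
      m <- matrix(as.numeric(m), ncol = 2)
      b <- base(m)
      tx <- (m[, 1] - dom$x[1]) / diff(dom$x)
      ty <- (m[, 2] - dom$y[1]) / diff(dom$y)
      cbind(b[, 1] + w * diff(azr) * sin(pi * tx) * 0.5,
            b[, 2] + w * diff(elr) * sin(pi * ty) * 0.5)
    }
    jac <- function(m) {
      m <- matrix(as.numeric(m), ncol = 2)
      tx <- (m[, 1] - dom$x[1]) / diff(dom$x)
      ty <- (m[, 2] - dom$y[1]) / diff(dom$y)
      dazdx <- ax * (1 + w * pi * cos(pi * tx) * 0.5)
      deldy <- ex * (1 + w * pi * cos(pi * ty) * 0.5)
      dazdx * deldy
    }
  } else stop("gen_retinotopy: unknown type '", cr$type, "'", call. = FALSE)
  structure(list(fun = fun, type = cr$type, domain = dom, jacobian = jac,
                 azimuth_range = azr, elevation_range = elr),
            class = "retinotopy")
}
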