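test_that("principal axes recover known directions and variance splits", {
  # collinear points: pc1 along the line, all variance on it
  t <- seq(-5, 5, length.out = 50)
  line <- cbind(t * cos(pi / 6), t * sin(pi / 6))
  ax <- pca_axes(line)
  expect_equal(atan2(ax$pc1[2], ax$pc1[1]) * 180 / pi, 30, tolerance = 1e-6)
  expect_equal(ax$explained, c(1, 0), tolerance = 1e-9)
  # isotropic cloud: even split
  set.seed(51)
  iso <- matrix(rnorm(2e4), ncol = 2)
  expect_equal(pca_axes(iso)$explained, c(0.5, 0.5), tolerance = 0.02)
  # configured 80/20 cloud
  cl <- gen_cell_cloud(generator_config(seed = 52, cloud = list(n = 10000L)))
  expect_equal(pca_axes(as.matrix(cl[, c("x", "y")]))$explained,
               c(0.8, 0.2), tolerance = 0.03)
  # sign convention: pc1 x-component never negative
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rnorm(200), ncol = 2) %*% matrix(rnorm(4), 2, 2)
    expect_gte(pca_axes(m)$pc1[1], 0)
  }
  expect_error(pca_axes(matrix(1, 5, 2)), "degenerate")
})

test_that("sectioning counts parcels per the anchored 200-unit rule", {
  # span of exactly 1000 along pc1: 5 separating boundaries, 6 sections
  pts <- cbind(seq(0, 1000, by = 5), 0)
  pr <- parcellate(pts, spacing = 200)
  expect_equal(nrow(pr$parcels), 6L)
  expect_equal(nrow(pr$section_lines), 5L)
  expect_equal(sum(pr$parcels$fraction), 1)
  # lines are parallel to pc2 and spaced exactly 200 apart along pc1
  sc <- pr$section_lines
  expect_true(all(abs(sc$dir_x * pr$axes$pc1[1] + sc$dir_y * pr$axes$pc1[2]) < 1e-9))
  pos <- (sc$point_x - pr$axes$center[1]) * pr$axes$pc1[1] +
    (sc$point_y - pr$axes$center[2]) * pr$axes$pc1[2]
  expect_equal(diff(pos), rep(200, 4))
  # identical points: a single parcel holding everything
  one <- parcellate(matrix(5, 10, 2) + 0, spacing = 200,
                    axes = list(pc1 = c(1, 0), pc2 = c(0, 1),
                                explained = c(0.5, 0.5), center = c(5, 5)))
  expect_equal(nrow(one$parcels), 1L)
  expect_equal(one$parcels$fraction, 1)
})

test_that("points exactly on a section line fall on the lower-score side", {
  axes <- list(pc1 = c(1, 0), pc2 = c(0, 1), explained = c(1, 0),
               center = c(0, 0))
  pts <- cbind(c(0, 100, 200, 250, 400, 401), 0)
  pr <- parcellate(pts, axes = axes, spacing = 200)
  b <- pr$parcels$bin1[pr$assignment]
  # 0 anchors bin 0; 200 lies on the first spacing line -> lower side (bin 1)
  expect_equal(b, c(0, 1, 1, 2, 2, 3))
})

test_that("parcellation is equivariant under rigid rotation", {
  set.seed(61)
  pts <- cbind(rnorm(800, sd = 300), rnorm(800, sd = 90))
  pr1 <- parcellate(pts, spacing = 200)
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pr2 <- parcellate(pts %*% t(R), spacing = 200)
  expect_equal(sort(pr2$parcels$fraction), sort(pr1$parcels$fraction))
  expect_equal(nrow(pr2$parcels), nrow(pr1$parcels))
})

test_that("the cross grid assigns every cell to exactly one parcel", {
  set.seed(62)
  pts <- cbind(rnorm(1000, sd = 300), rnorm(1000, sd = 150))
  pr <- parcellate(pts, spacing = 200, cross = TRUE)
  expect_equal(length(pr$assignment), nrow(pts))
  expect_false(anyNA(pr$assignment))
  expect_equal(sum(pr$parcels$n), nrow(pts))
  expect_equal(sum(pr$parcels$fraction), 1)
  expect_true(any(pr$section_lines$family == 2))
})

test_that("density maps recover cluster structure and normalize", {
  set.seed(71)
  ctr <- c(500, 480)
  pts <- cbind(rnorm(2000, ctr[1], 50), rnorm(2000, ctr[2], 50))
  dm <- density_map(pts, grid_step = 58)
  # argmax within one grid step of the generating mean
  expect_lt(sqrt(sum((dm$argmax - ctr)^2)), 58)
  # KDE integrates to 1 over the padded grid
  riemann <- sum(dm$z_pad) * dm$grid_step^2
  expect_equal(riemann, 1, tolerance = 0.05)
  expect_true(all(dm$z >= 0))
  # translation equivariance of the argmax
  dm2 <- density_map(sweep(pts, 2, c(-1000, 250), `-`), grid_step = 58)
  expect_equal(unname(dm2$argmax), unname(dm$argmax - c(-1000, 250)),
               tolerance = 1e-9)
  # mirroring the input mirrors the density field exactly
  dmm <- density_map(cbind(-pts[, 1], pts[, 2]), grid_step = 58)
  expect_equal(dmm$z_pad, dm$z_pad[rev(seq_along(dm$x_pad)), ],
               tolerance = 1e-9)
  expect_warning(density_map(cbind(1:50, 1:50)), "singular")
})

test_that("the relative fraction index follows its defining arithmetic", {
  r <- matrix(0L, 20, 20)
  r[1:10, 1:10] <- 1L # one barrel, 100 of 400 pixels
  m <- barrel_map(r)
  cells <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 10),
                      layer = "L2/3")
  expect_equal(unname(barrel_fraction_index(cells, m)[1, 1]), 4)
  # two barrels 100 + 300 px, counts 10 + 10 -> fr = (2, 2/3)
  r2 <- matrix(0L, 20, 20); r2[1:5, ] <- 1L; r2[6:20, ] <- 2L
  c2 <- data.frame(x = c(runif(10, 0, 5), runif(10, 5, 20)),
                   y = runif(20, 0, 20), layer = "L6")
  expect_equal(unname(barrel_fraction_index(c2, barrel_map(r2))[, 1]),
               c(2, 2 / 3), tolerance = 1e-12)
  # counts proportional to areas in one layer, other layer empty -> all 1
  r3 <- matrix(0L, 40, 40)
  r3[1:10, 1:10] <- 1L; r3[11:30, 1:20] <- 2L # areas 100 and 400, field 1600
  m3 <- barrel_map(r3)
  c3 <- data.frame(
    x = c(runif(10, 0, 10), runif(40, 10, 30), runif(110, 30, 40)),
    y = c(runif(10, 0, 10), runif(40, 0, 20), runif(110, 0, 40)),
    layer = "L2/3")
  fr3 <- barrel_fraction_index(c3, m3)
  expect_equal(unname(fr3[, 1]), c(1, 1), tolerance = 1e-12)
  # invariant under uniform raster rescaling (areas and counts co-scale)
  r4 <- r3[rep(1:40, each = 2), rep(1:40, each = 2)] # 2x resolution
  c4 <- transform(c3, x = 2 * x, y = 2 * y)
  expect_equal(barrel_fraction_index(c4, barrel_map(r4))[, 1], fr3[, 1],
               tolerance = 1e-12)
  expect_error(barrel_fraction_index(c3[0, ], m3), "no cells")
})

test_that("the permutation p-value observes the add-one bound", {
  cfg <- generator_config(seed = 81, barrel = list(n_cells = 500L))
  bg <- gen_barrel_map(cfg)
  pt <- barrel_permutation_test(bg$cells, bg$map, n_shuffles = 200,
                                seed = 81)
  expect_true(all(pt$p > 0 & pt$p <= 1))
  expect_gte(min(pt$p), 1 / 201)
  expect_identical(pt$significant, pt$p < pt$alpha)
  expect_equal(dim(pt$null[["L2/3"]]), c(200L, 20L))
  expect_error(barrel_permutation_test(bg$cells, bg$map, n_shuffles = 50,
                                       seed = 1), "100")
  expect_error(barrel_permutation_test(bg$cells, bg$map), "seed")
})

test_that("permutation rejections are calibrated under a light uniform null", {
  # reduced-size calibration (the full published-size run lives with the
  # acceptance checks): 40 runs x 500 shuffles at nominal alpha 0.05
  cfg <- generator_config(seed = 91, barrel = list(n_cells = 1000L,
                                                   layer_split = c(1, 0)))
  bg <- gen_barrel_map(cfg)
  rej <- vapply(1:40, function(i) {
    cells <- data.frame(x = runif(1000, 0, 400), y = runif(1000, 0, 400),
                        layer = "L2/3")
    pt <- barrel_permutation_test(cells, bg$map, n_shuffles = 500,
                                  alpha = 0.05, seed = 1000 + i)
    mean(pt$p < 0.05)
  }, numeric(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("a strongly enriched barrel is detected", {
  cfg <- generator_config(seed = 95,
                          barrel = list(n_cells = 2000L,
                                        layer_split = c(1, 0),
                                        enrichment = c(`13` = 5)))
  bg <- gen_barrel_map(cfg)
  pt <- barrel_permutation_test(bg$cells, bg$map, seed = 95)
  expect_true(pt$significant["13", 1])
  expect_lt(sum(pt$significant[rownames(pt$significant) != "13", ]), 2)
  # max-statistic mode is more conservative, never less
  ptm <- barrel_permutation_test(bg$cells, bg$map, seed = 95,
                                 correction = "max-stat")
  expect_true(all(ptm$p >= pt$p - 1e-12))
})

test_that("parcel visual coverage maps parcels through the retinotopy", {
  set.seed(97)
  pts <- cbind(runif(2000, 100, 900), runif(2000, 100, 900))
  pr <- parcellate(pts, spacing = 200, cross = TRUE)
  # identity retinotopy: patches congruent to the cortical parcels
  rid <- gen_retinotopy(generator_config(
    seed = 1, retinotopy = list(type = "identity",
                                domain = list(x = c(-500, 1500),
                                              y = c(-500, 1500)))))
  cov_id <- parcel_visual_coverage(pr, rid, threshold = 0)
  for (p in cov_id$patches)
    expect_equal(p$polygon, p$cortical, tolerance = 1e-12)
  # corner parcels of a rotated grid can poke beyond a tight domain:
  # they are excluded with a warning
  tight <- gen_retinotopy(generator_config(seed = 1))
  warns <- capture_warnings(
    cov_t <- parcel_visual_coverage(pr, tight, threshold = 0))
  expect_true(all(grepl("outside retinotopy domain", warns)))
  expect_gt(length(cov_t$excluded), 0)
  # affine retinotopy over a generous domain: patch areas scale by the
  # Jacobian determinant
  raf <- gen_retinotopy(generator_config(
    seed = 1, retinotopy = list(domain = list(x = c(-500, 1500),
                                              y = c(-500, 1500)))))
  cov_af <- parcel_visual_coverage(pr, raf, threshold = 0)
  detJ <- raf$jacobian(cbind(500, 500))
  for (p in cov_af$patches) {
    a_c <- polygon_area(p$cortical)
    a_v <- polygon_area(p$polygon)
    expect_equal(a_v / a_c, detJ, tolerance = 1e-9)
  }
  # merged region equals the brute-force preimage-threshold region
  cov <- parcel_visual_coverage(pr, raf, threshold = 0.05)
  grid <- as.matrix(expand.grid(x = seq(110, 890, by = 26),
                                y = seq(110, 890, by = 26)))
  # classify each grid point by its parcel's fraction, away from edges
  ax <- pr$axes
  s1 <- drop(sweep(grid, 2, ax$center) %*% ax$pc1)
  s2 <- drop(sweep(grid, 2, ax$center) %*% ax$pc2)
  bin_of <- function(s, r) {
    d <- s - r[1]
    b <- ceiling(d / 200 - 1e-9); b[d <= 1e-9] <- 0L
    b
  }
  b1 <- bin_of(s1, pr$score_range$s1); b2 <- bin_of(s2, pr$score_range$s2)
  edge_dist <- pmin(abs((s1 - pr$score_range$s1[1]) %% 200),
                    200 - abs((s1 - pr$score_range$s1[1]) %% 200),
                    abs((s2 - pr$score_range$s2[1]) %% 200),
                    200 - abs((s2 - pr$score_range$s2[1]) %% 200))
  keep <- edge_dist > 2 &
    s1 > pr$score_range$s1[1] & s1 < pr$score_range$s1[2] &
    s2 > pr$score_range$s2[1] & s2 < pr$score_range$s2[2]
  key <- paste(b1, b2, sep = ":")
  pk <- paste(pr$parcels$bin1, pr$parcels$bin2, sep = ":")
  frac <- pr$parcels$fraction[match(key, pk)]
  expected <- !is.na(frac) & frac >= 0.05
  vis <- raf$fun(grid)
  got <- cov$in_merged(vis[, 1], vis[, 2])
  expect_equal(got[keep], expected[keep])
})
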