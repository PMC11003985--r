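test_that("whisker construction honors its invariants", {
  w <- whisker("C", 2, c(14, 6, 0), phi_w = 5, theta_w = 95, zeta_w = 10,
               length = 20, curvature = 0.03)
  expect_equal(w$polyline[1, ], w$basepoint)
  # cumulative chord length within 1% of the declared arc length
  expect_lt(abs(polyline_length(w$polyline) - w$length) / w$length, 0.01)
  expect_equal(whisker_tip(w), w$polyline[nrow(w$polyline), ])
  # straight whisker: tip at base + L * tangent
  ws <- straight_whisker(length = 10, phi_w = 0, theta_w = 90)
  expect_equal(whisker_tip(ws), c(0, 10, 0), tolerance = 1e-12)
})

test_that("the twist angle selects the curvature plane as documented", {
  # lateral whisker (tangent +y): zeta 0 curves ventrally, 180 dorsally,
  # +90 rostrally, -90 caudally
  tip_of <- function(zeta) whisker_tip(
    whisker("C", 1, c(0, 0, 0), 0, 90, zeta, length = 10, curvature = 0.05))
  expect_lt(tip_of(0)[3], -0.5)    # ventral = -z
  expect_gt(tip_of(180)[3], 0.5)   # dorsal = +z
  expect_gt(tip_of(90)[1], 0.5)    # rostral = +x
  expect_lt(tip_of(-90)[1], -0.5)  # caudal = -x
})

test_that("eye-centered spherical conversion matches an explicit construction", {
  eye <- c(6, 4.5, 3.5)
  arr <- gen_whisker_array(generator_config(seed = 5))
  # a point on the nose-ward axis in the horizontal plane
  p0 <- to_eye_spherical(eye + c(12, 0, 0), arr)
  expect_equal(unlist(p0[c("r", "azimuth", "elevation")]),
               c(r = 12, azimuth = 0, elevation = 0))
  # the pole above the eye
  pp <- to_eye_spherical(eye + c(0, 0, 7), arr)
  expect_equal(pp$elevation, 90)
  expect_true(pp$pole)
  expect_equal(pp$azimuth, 0)
  # arbitrary angles: construct the point from (r, az, el) and recover them
  set.seed(9)
  for (i in 1:20) {
    r <- runif(1, 5, 40); az <- runif(1, -170, 170); el <- runif(1, -80, 80)
    pt <- eye + r * c(cos(el * pi / 180) * cos(az * pi / 180),
                      cos(el * pi / 180) * sin(az * pi / 180),
                      sin(el * pi / 180))
    got <- to_eye_spherical(pt, arr)
    expect_equal(unlist(got[c("r", "azimuth", "elevation")]),
                 c(r = r, azimuth = az, elevation = el), tolerance = 1e-9)
  }
  expect_error(to_eye_spherical(eye, arr), "coincides")
})

test_that("whisking-plane fitting recovers known planes", {
  # coplanar construction: straight whiskers in the y = const plane
  mk <- function(x, z, phi) straight_whisker(length = 15, phi_w = phi,
                                             theta_w = 0, zeta_w = 0,
                                             basepoint = c(x, 3, z))
  row <- list(mk(0, 0, 10), mk(1, 1, 12), mk(2, 2, 8), mk(3, 3, 11))
  # tangents lie in vertical planes y = 3: all bases and tips coplanar? No:
  # theta_w = 0 keeps y fixed at 3 for every point, so the plane is y = 3.
  pl <- fit_whisking_plane(row, row = "A")
  resid <- abs(c(vapply(row, function(w) w$basepoint[2], numeric(1)),
                 vapply(row, function(w) whisker_tip(w)[2], numeric(1))) - 3)
  expect_lt(max(resid), 1e-12)
  expect_equal(abs(pl$normal), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(abs(sum(pl$normal * pl$in_plane_mean)), 1e-9)

  # jittered plane: normal recovered within 2 degrees (SVD oracle)
  set.seed(31)
  n_true <- c(0.2, 0.95, -0.1); n_true <- n_true / sqrt(sum(n_true^2))
  e1 <- c(1, 0, 0) - n_true[1] * n_true; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n_true[2] * e1[3] - n_true[3] * e1[2],
          n_true[3] * e1[1] - n_true[1] * e1[3],
          n_true[1] * e1[2] - n_true[2] * e1[1])
  lens <- c(22, 18, 15, 12, 9)          # caudal-to-rostral length schedule
  dirs <- c(70, 62, 55, 48, 40) * pi / 180 # in-plane emergence directions
  ws <- lapply(1:5, function(i) {
    base <- 1.5 * i * e1 + rnorm(3, 0, 0.05)
    dirv <- cos(dirs[i]) * e1 + sin(dirs[i]) * e2
    phi <- asin(dirv[3]) * 180 / pi
    th <- atan2(dirv[2], dirv[1]) * 180 / pi
    straight_whisker(length = lens[i], phi_w = phi, theta_w = th,
                     basepoint = base)
  })
  pl2 <- fit_whisking_plane(ws, row = "B")
  ang <- acos(min(abs(sum(pl2$normal * n_true)), 1)) * 180 / pi
  expect_lt(ang, 2)

  # two-whisker row constructed coplanar: zero residual for all 4 points
  two <- list(mk(0, 0, 10), mk(2, 1, 15))
  pl3 <- fit_whisking_plane(two, row = "C")
  pts <- rbind(t(vapply(two, function(w) w$basepoint, numeric(3))),
               t(vapply(two, whisker_tip, numeric(3))))
  resid3 <- abs(sweep(pts, 2, pl3$centroid) %*% pl3$normal)
  expect_lt(max(resid3), 1e-9)

  # collinear degenerate input is refused
  col <- list(straight_whisker(basepoint = c(0, 0, 0), phi_w = 0, theta_w = 90),
              straight_whisker(basepoint = c(0, 5, 0), phi_w = 0, theta_w = 90))
  expect_error(fit_whisking_plane(col, row = "D"), "degenerate|collinear")
})

test_that("in-plane rotation is an exact isometry with a fixed basepoint", {
  arr <- gen_whisker_array(generator_config(seed = 13))
  planes <- fit_whisking_planes(arr)
  expect_named(planes, c("A", "B", "C", "D", "E"))
  for (pl in planes) {
    expect_lt(abs(sum(pl$normal * pl$in_plane_mean)), 1e-9)
    expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)
  }
  a0 <- rotate_in_plane(arr, 0, planes)
  expect_identical(array_tips(a0), array_tips(arr)) # identity at 0 degrees
  fwd <- rotate_in_plane(arr, 40, planes)
  back <- rotate_in_plane(fwd, -40, planes)
  for (id in names(arr$whiskers)) {
    expect_lt(max(abs(back$whiskers[[id]]$polyline - arr$whiskers[[id]]$polyline)),
              1e-9)
    expect_equal(fwd$whiskers[[id]]$basepoint, arr$whiskers[[id]]$basepoint)
    expect_lt(max_pairwise_dist_change(arr$whiskers[[id]], fwd$whiskers[[id]]),
              1e-9)
  }
  # positive angles are protraction: tips move nose-ward on average
  expect_gt(mean(array_tips(fwd)[, 1]), mean(array_tips(arr)[, 1]))
})

test_that("plane inclination rotates normals per the axis-angle formula", {
  arr <- gen_whisker_array(generator_config(seed = 17))
  planes <- fit_whisking_planes(arr)
  same <- incline_planes(planes, 0)
  for (rw in names(planes))
    expect_equal(same[[rw]]$normal, planes[[rw]]$normal)
  up <- incline_planes(planes, 20)
  for (rw in names(planes)) {
    pl <- planes[[rw]]
    # Rodrigues rotation of the normal about the in-plane mean direction
    k <- pl$in_plane_mean; v <- pl$normal; a <- 20 * pi / 180
    kxv <- c(k[2] * v[3] - k[3] * v[2], k[3] * v[1] - k[1] * v[3],
             k[1] * v[2] - k[2] * v[1])
    expected <- v * cos(a) + kxv * sin(a) + k * sum(k * v) * (1 - cos(a))
    expect_equal(up[[rw]]$normal, expected, tolerance = 1e-12)
    expect_equal(sqrt(sum(up[[rw]]$normal^2)), 1, tolerance = 1e-12)
    expect_lt(abs(sum(up[[rw]]$normal * up[[rw]]$in_plane_mean)), 1e-9)
  }
  down <- incline_planes(up, -20)
  for (rw in names(planes))
    expect_equal(down[[rw]]$normal, planes[[rw]]$normal, tolerance = 1e-12)
})

test_that("roll spins whiskers about their own axis, leaving base and tip put", {
  arr <- gen_whisker_array(generator_config(seed = 23))
  rolled <- apply_roll(arr, scale = 1)
  for (id in names(arr$whiskers)) {
    expect_equal(rolled$whiskers[[id]]$basepoint, arr$whiskers[[id]]$basepoint)
    expect_lt(max(abs(whisker_tip(rolled$whiskers[[id]]) -
                        whisker_tip(arr$whiskers[[id]]))), 1e-9)
    expect_lt(max_pairwise_dist_change(arr$whiskers[[id]],
                                       rolled$whiskers[[id]]), 1e-9)
  }
  # a full turn is the identity
  full <- apply_roll(arr, scale = 1,
                     roll_angles = c(A = 360, B = 360, C = 360, D = 360, E = 360))
  for (id in names(arr$whiskers))
    expect_lt(max(abs(full$whiskers[[id]]$polyline -
                        arr$whiskers[[id]]$polyline)), 1e-6)
  # the A-row midpoint moves as a -36.8 degree rotation about the chord
  w <- arr$whiskers[["A1"]]
  mid <- w$polyline[25, ]
  expected <- drop(rotation_matrix(whisker_tip(w) - w$basepoint, -36.8) %*%
                     (mid - w$basepoint)) + w$basepoint
  expect_equal(rolled$whiskers[["A1"]]$polyline[25, ], expected,
               tolerance = 1e-12)
})

test_that("scenario composition at 0/0/0 returns the input bit-identically", {
  arr <- gen_whisker_array(generator_config(seed = 29))
  posed <- pose_array(arr, 0, inclination_deg = 0, roll_scale = 0)
  expect_identical(lapply(posed$whiskers, `[[`, "polyline"),
                   lapply(arr$whiskers, `[[`, "polyline"))
})

test_that("tip-in-visual-space fractions follow the polygon", {
  arr <- gen_whisker_array(generator_config(seed = 37))
  # a polygon covering the whole sane angular domain contains every tip
  all_map <- visual_space_map(rbind(c(-30, -60), c(120, -60),
                                    c(120, 90), c(-30, 90)))
  expect_equal(tips_in_space(arr, all_map)$fraction, 1.0)
  # a degenerate-area triangle far from every tip contains none
  none_map <- visual_space_map(rbind(c(-30, 89), c(-29, 89), c(-30, 90)))
  expect_equal(tips_in_space(arr, none_map)$fraction, 0.0)
  # constructed placement: exactly 3 of 24 tips inside a unit square
  azel <- cbind(seq(10, 56, by = 2), rep(50, 24))
  azel[1:3, ] <- cbind(c(0.2, 0.5, 0.8), c(0.3, 0.6, 0.9))
  arr2 <- array_with_tips(azel)
  sq <- visual_space_map(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  res <- tips_in_space(arr2, sq)
  expect_equal(res$fraction, 3 / 24)
  expect_equal(sum(res$inside), 3L)
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(41)
  poly <- cbind(c(0, 4, 5, 3, 1, -1), c(0, -1, 3, 5, 4, 2))
  px <- runif(300, -2, 6); py <- runif(300, -2, 6)
  mine <- point_in_polygon(px, py, poly)
  ref <- as.logical(mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py)))
  # compare away from the boundary (tie rules differ there by design)
  d <- dist_to_polygon(px, py, poly)
  far <- d > 1e-6
  expect_equal(mine[far], ref[far])
  # boundary points count as inside here
  expect_true(all(point_in_polygon(c(0, 2), c(0, -0.5), poly)))
})

test_that("polygon dilation admits nearby outside points only", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_false(in_dilated_polygon(12, 5, sq, 0))
  expect_true(in_dilated_polygon(12, 5, sq, 2))
  expect_false(in_dilated_polygon(12.5, 5, sq, 2))
  # corner distance is Euclidean
  expect_true(in_dilated_polygon(11, 11, sq, 2))
  expect_false(in_dilated_polygon(11.5, 11.5, sq, 2))
})

test_that("tip uncertainty propagates the angle box in quadrature", {
  # no angular perturbation: only the basepoint floor remains
  w <- straight_whisker(length = 15)
  u0 <- propagate_tip_uncertainty(w, d_angle = 0, d_zeta = 0)
  expect_equal(u0$sphere_radius, 0.5)
  # straight whisker, azimuth-only: chord formula 2 L sin(1 deg)
  u_th <- propagate_tip_uncertainty(w, d_angle = 2, d_zeta = 0)
  expect_equal(u_th$components[["theta"]], 2 * 15 * sin(pi / 180),
               tolerance = 1e-9)
  expect_equal(u_th$components[["phi"]], 2 * 15 * sin(pi / 180),
               tolerance = 1e-9)
  # a straight whisker is invariant under twist
  expect_equal(u_th$components[["zeta"]], 0)
  # radius grows with whisker length at fixed angles
  radii <- vapply(c(5, 10, 20, 30), function(L)
    propagate_tip_uncertainty(straight_whisker(length = L))$sphere_radius,
    numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("uncertainty spheres match a Monte-Carlo box oracle within 25%", {
  arr <- gen_whisker_array(generator_config(seed = 43))
  set.seed(43)
  for (id in c("A1", "C3", "E4", "greekalpha")) {
    w <- arr$whiskers[[id]]
    u <- propagate_tip_uncertainty(w)
    tip0 <- w$polyline[nrow(w$polyline), ]
    draws <- cbind(runif(1e4, -2, 2), runif(1e4, -2, 2), runif(1e4, -4, 4))
    disp <- vapply(seq_len(nrow(draws)), function(i) {
      wp <- whisker(w$id$row, w$id$arc, w$basepoint,
                    w$phi_w + draws[i, 1], w$theta_w + draws[i, 2],
                    w$zeta_w + draws[i, 3], w$length, w$curvature,
                    n_points = 50L)
      sqrt(sum((wp$polyline[nrow(wp$polyline), ] - tip0)^2))
    }, numeric(1))
    mc_radius <- max(disp) + 0.5
    expect_lt(abs(u$sphere_radius - mc_radius) / mc_radius, 0.25)
  }
})

test_that("arc summaries aggregate lengths and eye distances per arc", {
  arr <- gen_whisker_array(generator_config(seed = 47))
  s1 <- arc_summary(arr)
  expect_equal(s1$arc, c("greek", "1", "2", "3", "4"))
  expect_true(all(s1$sem_length == 0) && all(s1$sem_r_tip == 0))
  expect_equal(sum(s1$n_whiskers), 24L)
  # caudal-most arcs are the longest in the default generator
  expect_true(all(diff(s1$mean_length) < 0))
  # identical replicated arrays have zero s.e.m.
  s3 <- arc_summary(list(arr, arr, arr))
  expect_true(all(s3$sem_length == 0) && all(s3$sem_r_tip == 0))
  expect_equal(s3$mean_length, s1$mean_length)
  # across different animals the s.e.m. is positive
  arrs <- lapply(c(47, 48, 49), function(s)
    gen_whisker_array(generator_config(seed = s)))
  s5 <- arc_summary(arrs)
  expect_true(all(s5$sem_length > 0))
})

test_that("protraction does not reduce visual-field overlap vs retraction", {
  arr <- gen_whisker_array(generator_config(seed = 1))
  map <- gen_visual_space(generator_config(seed = 1), dilation = 20)
  fr_re <- tips_in_space(pose_array(arr, -40), map)$fraction
  fr_pro <- tips_in_space(pose_array(arr, 40), map)$fraction
  expect_gte(fr_pro, fr_re)
})
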