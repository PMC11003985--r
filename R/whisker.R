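#' A single parametric 3D whisker
#'
#' Builds a whisker as a constant-curvature planar arc of exact arc length,
#' sampled as an `n_points` polyline from base to tip. The emergence
#' direction is set by the azimuth (`theta_w`) and elevation (`phi_w`)
#' angles of the initial tangent in the head frame (x nose-ward, y toward
#' the left-lateral side, z up; horizontal plane parallel to the
#' bregma-lambda plane). The twist angle `zeta_w` selects the curvature
#' plane: 0 deg is ventrally directed curvature, 180 deg dorsal, +90 deg
#' rostral and -90 deg caudal.
#'
#' @param row row id, one of `"A".."E"` or `"greek"`.
#' @param arc arc id: `1:4` or `"greek"`.
#' @param basepoint 3-vector (mm).
#' @param phi_w emergence elevation angle (deg, from the horizontal plane).
#' @param theta_w emergence azimuth angle (deg, from the nose-ward axis in
#'   the horizontal plane, positive toward left-lateral/caudal).
#' @param zeta_w twist angle (deg).
#' @param length arc length (mm, > 0).
#' @param curvature planar curvature (1/mm, >= 0); 0 gives a straight whisker.
#' @param n_points polyline samples.
#' @return an object of class `"whisker"`.
#' @export
whisker <- function(row, arc, basepoint, phi_w, theta_w, zeta_w,
                    length, curvature = 0.025, n_points = 50L) {
  stopifnot(length > 0, curvature >= 0, n_points >= 2)
  basepoint <- as.numeric(basepoint)
  tangent <- emergence_tangent(phi_w, theta_w)
  normal0 <- curvature_normal(tangent, zeta_w)
  s <- seq(0, length, length.out = n_points)
  if (curvature < 1e-12) {
    poly <- outer(s, tangent) # n x 3
    poly <- sweep(poly, 2, basepoint, `+`)
  } else {
    k <- curvature
    poly <- outer(sin(k * s) / k, tangent) +
      outer((1 - cos(k * s)) / k, normal0)
    poly <- sweep(poly, 2, basepoint, `+`)
  }
  w <- list(id = list(row = row, arc = arc),
            basepoint = basepoint,
            phi_w = phi_w, theta_w = theta_w, zeta_w = zeta_w,
            length = length, curvature = curvature,
            polyline = poly)
  class(w) <- "whisker"
  w
}

# initial tangent direction from emergence angles
emergence_tangent <- function(phi_w, theta_w) {
  ph <- deg2rad(phi_w); th <- deg2rad(theta_w)
  c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
}

# in-plane curvature normal: zeta = 0 -> ventral (-z) component,
# rotated about the tangent so that +90 deg is rostral (+x) for a
# left-lateral whisker
curvature_normal <- function(tangent, zeta_w) {
  down <- c(0, 0, -1)
  n0 <- down - sum(down * tangent) * tangent
  if (vnorm(n0) < 1e-9) {
    # vertical whisker: ventral reference undefined, fall back to -x
    n0 <- c(-1, 0, 0) - sum(c(-1, 0, 0) * tangent) * tangent
  }
  n0 <- unitize(n0)
  drop(rotation_matrix(tangent, -zeta_w) %*% n0)
}

#' @export
print.whisker <- function(x, ...) {
  cat(sprintf("whisker %s%s: L = %.1f mm, base (%.1f, %.1f, %.1f), angles (phi %.1f, theta %.1f, zeta %.1f) deg\n",
              x$id$row, x$id$arc, x$length,
              x$basepoint[1], x$basepoint[2], x$basepoint[3],
              x$phi_w, x$theta_w, x$zeta_w))
  invisible(x)
}

whisker_tip <- function(w) w$polyline[nrow(w$polyline), ]

whisker_id_string <- function(w) paste0(w$id$row, w$id$arc)

polyline_length <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

#' The full whisker array
#'
#' A set of 24 large whiskers (rows A-E x arcs 1-4 plus the four caudal
#' greek whiskers alpha-delta) together with the left-eye position and the
#' head reference frame.
#'
#' @param whiskers list of 24 [whisker()] objects with unique ids.
#' @param eye 3-vector, left-eye center (mm).
#' @param frame 3x3 orthonormal matrix whose rows are the head-frame axes
#'   (x nose-ward, y left-lateral, z up); default identity.
#' @return an object of class `"whisker_array"`.
#' @export
whisker_array <- function(whiskers, eye, frame = diag(3)) {
  ids <- vapply(whiskers, whisker_id_string, character(1))
  if (length(whiskers) != 24L)
    stop("whisker_array: exactly 24 whiskers required, got ", length(whiskers),
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("whisker_array: duplicated whisker ids", call. = FALSE)
  if (!all(is.finite(eye)) || !all(is.finite(frame)))
    stop("whisker_array: eye and frame must be finite", call. = FALSE)
  structure(list(whiskers = stats::setNames(whiskers, ids),
                 eye = as.numeric(eye), frame = frame),
            class = "whisker_array")
}

#' @export
print.whisker_array <- function(x, ...) {
  cat(sprintf("whisker array: %d whiskers, eye at (%.1f, %.1f, %.1f) mm\n",
              length(x$whiskers), x$eye[1], x$eye[2], x$eye[3]))
  invisible(x)
}

array_tips <- function(array) {
  t(vapply(array$whiskers, whisker_tip, numeric(3)))
}

#' Eye-centered spherical coordinates
#'
#' Converts 3D head-frame points to spherical coordinates centered on the
#' left eye: `r` is the Euclidean distance to the eye, elevation is
#' measured from the horizontal (bregma-lambda) plane, positive up, and
#' azimuth is measured in the horizontal plane from the nose-ward axis,
#' positive toward the left-lateral/caudal side.
#'
#' @param points 3-vector or n x 3 matrix (mm).
#' @param array a [whisker_array()] providing the eye and frame.
#' @return data.frame with columns `r` (mm), `azimuth`, `elevation` (deg)
#'   and `pole` (TRUE where the point is directly above/below the eye, in
#'   which case azimuth is reported as 0).
#' @export
to_eye_spherical <- function(points, array) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  v <- sweep(points, 2, array$eye) %*% t(array$frame)
  r <- sqrt(rowSums(v^2))
  if (any(r < .Machine$double.eps * 64))
    stop("to_eye_spherical: point coincides with the eye", call. = FALSE)
  el <- rad2deg(asin(pmin(pmax(v[, 3] / r, -1), 1)))
  pole <- abs(v[, 1]) < 1e-12 & abs(v[, 2]) < 1e-12
  az <- ifelse(pole, 0, rad2deg(atan2(v[, 2], v[, 1])))
  data.frame(r = r, azimuth = az, elevation = el, pole = pole)
}

#' Best-fit whisking plane of a row
#'
#' Fits a least-squares plane through the basepoints and tips of a row's
#' whiskers (total least squares via SVD of the centered coordinates). The
#' plane normal is the rotation axis used for retraction/protraction; the
#' in-plane mean direction is the normalized average base-to-tip vector
#' projected into the plane. The normal is oriented so that a positive
#' in-plane rotation moves tips rostrally (protraction convention).
#'
#' @param row_whiskers list of >= 2 [whisker()] objects.
#' @param row row label carried in the result.
#' @return an object of class `"whisking_plane"`: list with `row`,
#'   `normal`, `in_plane_mean`, `inclination` (deg, 0 on construction) and
#'   `centroid`.
#' @export
fit_whisking_plane <- function(row_whiskers, row = row_whiskers[[1]]$id$row) {
  if (length(row_whiskers) < 2)
    stop("fit_whisking_plane: need at least 2 whiskers", call. = FALSE)
  bases <- t(vapply(row_whiskers, function(w) w$basepoint, numeric(3)))
  tips <- t(vapply(row_whiskers, whisker_tip, numeric(3)))
  pts <- rbind(bases, tips)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: collinear points, whisking plane undefined",
         call. = FALSE)
  normal <- sv$v[, 3]
  mean_bt <- colMeans(tips - bases)
  in_plane <- mean_bt - sum(mean_bt * normal) * normal
  in_plane <- unitize(in_plane)
  # orient the normal so +angle rotation of the mean direction is rostral
  if (crossprod3(normal, in_plane)[1] < 0) normal <- -normal
  structure(list(row = row, normal = normal, in_plane_mean = in_plane,
                 inclination = 0, centroid = ctr),
            class = "whisking_plane")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit whisking planes for all rows of an array
#'
#' One plane per row A-E; the greek whiskers are included in (and later
#' rotated with) the plane of their corresponding row (alpha with A, beta
#' with B, gamma with C, delta with D).
#'
#' @param array a [whisker_array()].
#' @return named list of [fit_whisking_plane()] results, names `"A".."E"`.
#' @export
fit_whisking_planes <- function(array) {
  rows <- c("A", "B", "C", "D", "E")
  greek_row <- c(alpha = "A", beta = "B", gamma = "C", delta = "D")
  out <- lapply(rows, function(rw) {
    ws <- Filter(function(w) {
      w$id$row == rw ||
        (w$id$row == "greek" && greek_row[[as.character(w$id$arc)]] == rw)
    }, array$whiskers)
    fit_whisking_plane(ws, row = rw)
  })
  stats::setNames(out, rows)
}

#' Rotate whiskers within their whisking planes
#'
#' Retraction (negative angles) / protraction (positive angles): every
#' polyline point is rotated about the axis through the whisker basepoint
#' directed along the row's plane normal. Basepoints stay fixed, whisker
#' lengths and out-of-plane offsets are preserved (the rotation is an
#' isometry). Greek whiskers use the plane of their corresponding row.
#'
#' @param array a [whisker_array()].
#' @param angle_deg rotation angle (deg); the scenarios of interest span
#'   -40 (full retraction) to +40 (full protraction).
#' @param planes named list from [fit_whisking_planes()]; fitted on the fly
#'   when omitted.
#' @return a new `whisker_array` in the rotated pose.
#' @export
rotate_in_plane <- function(array, angle_deg, planes = NULL) {
  if (is.null(planes)) planes <- fit_whisking_planes(array)
  greek_row <- c(alpha = "A", beta = "B", gamma = "C", delta = "D")
  ws <- lapply(array$whiskers, function(w) {
    rw <- if (w$id$row == "greek") greek_row[[as.character(w$id$arc)]] else w$id$row
    pl <- planes[[rw]]
    if (is.null(pl)) stop("rotate_in_plane: missing plane for row ", rw,
                          call. = FALSE)
    w$polyline <- rotate_points(w$polyline, pl$normal, angle_deg,
                                pivot = w$basepoint)
    w
  })
  whisker_array(ws, array$eye, array$frame)
}

#' Change the inclination of whisking planes
#'
#' Each plane is rotated about its own in-plane mean direction by the
#' inclination angle; the normal stays unit length and perpendicular to the
#' in-plane direction. Whiskers themselves are not moved: inclination only
#' changes the axis along which a subsequent [rotate_in_plane()] sweeps.
#'
#' @param planes named list from [fit_whisking_planes()].
#' @param inclination_deg inclination angle (deg); the alternative-trajectory
#'   scenarios use -60, -40, -20, +20, +40, +60.
#' @return the inclined planes.
#' @export
incline_planes <- function(planes, inclination_deg) {
  lapply(planes, function(pl) {
    R <- rotation_matrix(pl$in_plane_mean, inclination_deg)
    pl$normal <- unitize(drop(R %*% pl$normal))
    pl$inclination <- pl$inclination + inclination_deg
    pl
  })
}

#' Row-specific roll about each whisker's longitudinal axis
#'
#' Rotates every whisker's polyline about the axis through its basepoint
#' along the base-to-tip chord, by `scale` times the row-specific roll
#' angle: A -36.8, B -14.0, C 23.8, D 16.2, E 26.7 degrees (applied after
#' protraction). Basepoint and tip are on the axis and therefore invariant.
#' Greek whiskers use the angle of their corresponding row (an assumption:
#' only rows A-E have measured roll angles).
#'
#' @param array a [whisker_array()].
#' @param scale roll scaling factor; the scenarios use 0.5, 1, 2.
#' @param roll_angles named vector of per-row angles (deg).
#' @return a new `whisker_array` with rolled whiskers.
#' @export
apply_roll <- function(array, scale = 1,
                       roll_angles = c(A = -36.8, B = -14.0, C = 23.8,
                                       D = 16.2, E = 26.7)) {
  greek_row <- c(alpha = "A", beta = "B", gamma = "C", delta = "D")
  ws <- lapply(array$whiskers, function(w) {
    rw <- if (w$id$row == "greek") greek_row[[as.character(w$id$arc)]] else w$id$row
    axis <- whisker_tip(w) - w$basepoint
    if (vnorm(axis) < 1e-9)
      stop("apply_roll: zero-length whisker ", whisker_id_string(w), call. = FALSE)
    w$polyline <- rotate_points(w$polyline, axis, scale * roll_angles[[rw]],
                                pivot = w$basepoint)
    w
  })
  whisker_array(ws, array$eye, array$frame)
}

#' Pose an array under a whisking scenario
#'
#' Composition order: incline the whisking planes, rotate whiskers within
#' the (possibly inclined) planes, then apply roll -- matching the
#' simulation narrative in which roll is applied after protraction.
#'
#' @param array a [whisker_array()] in the intermediate pose.
#' @param angle_deg in-plane rotation: -40 retraction, 0 intermediate,
#'   +40 protraction.
#' @param inclination_deg whisking-plane inclination (deg, default 0).
#' @param roll_scale roll scaling (default 0 = no roll).
#' @return the posed `whisker_array`.
#' @export
pose_array <- function(array, angle_deg, inclination_deg = 0, roll_scale = 0) {
  planes <- fit_whisking_planes(array)
  if (inclination_deg != 0) planes <- incline_planes(planes, inclination_deg)
  out <- if (angle_deg != 0) rotate_in_plane(array, angle_deg, planes) else array
  if (roll_scale != 0) out <- apply_roll(out, roll_scale)
  out
}

#' Fraction of whisker tips inside the visual-space coverage
#'
#' Converts the 24 whisker tips to eye-centered (azimuth, elevation)
#' coordinates and tests them against the visual-space polygon, optionally
#' dilated (eye-movement allowance). Tips exactly on the polygon boundary
#' count as inside.
#'
#' @param array a [whisker_array()].
#' @param map a [visual_space_map()].
#' @return list with `fraction` (inside count / 24), `inside` (named
#'   logical), and `tips` (the spherical tip coordinates).
#' @export
tips_in_space <- function(array, map) {
  stopifnot(inherits(map, "visual_space_map"))
  tips <- array_tips(array)
  sph <- to_eye_spherical(tips, array)
  ins <- in_dilated_polygon(sph$azimuth, sph$elevation, map$polygon,
                            map$dilation)
  names(ins) <- rownames(tips)
  list(fraction = mean(ins), inside = ins,
       tips = cbind(sph, id = rownames(tips)))
}

#' Tip-position uncertainty sphere
#'
#' Propagates measurement uncertainty in the emergence and twist angles to
#' the whisker tip. Six perturbed variants are generated (phi_w +/- d_angle,
#' theta_w +/- d_angle, zeta_w +/- d_zeta); for each source the uncertainty
#' is the mean Euclidean tip displacement of its +/- pair; the three source
#' components are combined in quadrature and the basepoint uncertainty is
#' added to give the sphere radius.
#'
#' @param w a [whisker()].
#' @param d_angle emergence-angle perturbation (deg, default 2).
#' @param d_zeta twist-angle perturbation (deg, default 4).
#' @param basepoint_err additive basepoint uncertainty (mm, default 0.5).
#' @return an object of class `"tip_uncertainty"`: list with `id`,
#'   `sphere_radius` (mm) and per-source `components` (mm).
#' @export
propagate_tip_uncertainty <- function(w, d_angle = 2, d_zeta = 4,
                                      basepoint_err = 0.5) {
  stopifnot(inherits(w, "whisker"))
  tip0 <- whisker_tip(w)
  rebuild <- function(dphi = 0, dtheta = 0, dzeta = 0) {
    whisker(w$id$row, w$id$arc, w$basepoint,
            w$phi_w + dphi, w$theta_w + dtheta, w$zeta_w + dzeta,
            w$length, w$curvature, nrow(w$polyline))
  }
  disp <- function(wp) vnorm(whisker_tip(wp) - tip0)
  comp <- c(
    phi = mean(c(disp(rebuild(dphi = d_angle)), disp(rebuild(dphi = -d_angle)))),
    theta = mean(c(disp(rebuild(dtheta = d_angle)), disp(rebuild(dtheta = -d_angle)))),
    zeta = mean(c(disp(rebuild(dzeta = d_zeta)), disp(rebuild(dzeta = -d_zeta)))))
  structure(list(id = whisker_id_string(w),
                 sphere_radius = sqrt(sum(comp^2)) + basepoint_err,
                 components = c(comp, basepoint = basepoint_err)),
            class = "tip_uncertainty")
}

#' Per-arc summary of whisker length and eye-to-tip distance
#'
#' Groups whiskers by arc (greek, 1..4) and reports, per arc, the mean
#' whisker length and mean eye-to-tip distance `r_tip`, with the s.e.m.
#' across arrays (0 for a single array). Empty groups are dropped with a
#' warning.
#'
#' @param arrays a single [whisker_array()] or a list of them (e.g. one per
#'   simulated animal, all in the same pose).
#' @return data.frame with columns `arc`, `n_whiskers`, `mean_length`,
#'   `sem_length`, `mean_r_tip`, `sem_r_tip`.
#' @export
arc_summary <- function(arrays) {
  if (inherits(arrays, "whisker_array")) arrays <- list(arrays)
  if (!length(arrays)) stop("arc_summary: need at least one array", call. = FALSE)
  per_array <- lapply(arrays, function(a) {
    arc <- vapply(a$whiskers, function(w) as.character(w$id$arc), character(1))
    arc[vapply(a$whiskers, function(w) w$id$row == "greek", logical(1))] <- "greek"
    len <- vapply(a$whiskers, function(w) w$length, numeric(1))
    r_tip <- to_eye_spherical(array_tips(a), a)$r
    data.frame(arc = arc, length = len, r_tip = r_tip)
  })
  arcs <- c("greek", "1", "2", "3", "4")
  rows <- lapply(arcs, function(ac) {
    per <- lapply(per_array, function(d) d[d$arc == ac, , drop = FALSE])
    ns <- vapply(per, nrow, integer(1))
    if (all(ns == 0)) {
      warning("arc_summary: empty arc group '", ac, "' omitted", call. = FALSE)
      return(NULL)
    }
    mlen <- vapply(per, function(d) mean(d$length), numeric(1))
    mr <- vapply(per, function(d) mean(d$r_tip), numeric(1))
    sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    data.frame(arc = ac, n_whiskers = sum(ns),
               mean_length = mean(mlen), sem_length = sem(mlen),
               mean_r_tip = mean(mr), sem_r_tip = sem(mr))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
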