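# Plain-text serialization of the pipeline's containers: CSV for point
# data and rasters, JSON sidecars for metadata. Round-trips are exact to
# full double precision (values are written with format(..., digits = 17)).

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write / read a whisker array
#'
#' The polylines go to a CSV (`whisker_id`, `point_index`, `x`, `y`, `z`);
#' the eye position, head frame and per-whisker parameters (ids, angles,
#' lengths, curvatures) go to a JSON header next to it (`<path>.json`).
#'
#' @param array a [whisker_array()].
#' @param path CSV file path; the header is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_whisker_array <- function(array, path) {
  stopifnot(inherits(array, "whisker_array"))
  rows <- do.call(rbind, lapply(names(array$whiskers), function(id) {
    pl <- array$whiskers[[id]]$polyline
    data.frame(whisker_id = id, point_index = seq_len(nrow(pl)) - 1L,
               x = fmt_num(pl[, 1]), y = fmt_num(pl[, 2]), z = fmt_num(pl[, 3]))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  header <- list(
    eye = array$eye, frame = array$frame,
    whiskers = lapply(array$whiskers, function(w)
      list(row = w$id$row, arc = as.character(w$id$arc),
           basepoint = w$basepoint, phi_w = w$phi_w, theta_w = w$theta_w,
           zeta_w = w$zeta_w, length = w$length, curvature = w$curvature)))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_whisker_array
#' @export
read_whisker_array <- function(path) {
  pts <- utils::read.csv(path)
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ws <- lapply(names(header$whiskers), function(id) {
    h <- header$whiskers[[id]]
    arc <- if (h$row == "greek") h$arc else as.integer(h$arc)
    w <- whisker(h$row, arc, h$basepoint, h$phi_w, h$theta_w, h$zeta_w,
                 h$length, h$curvature,
                 n_points = sum(pts$whisker_id == id))
    # the stored polyline is authoritative (it may be posed, not canonical)
    sub <- pts[pts$whisker_id == id, ]
    w$polyline <- unname(as.matrix(sub[order(sub$point_index),
                                       c("x", "y", "z")]))
    w$basepoint <- w$polyline[1, ]
    w
  })
  whisker_array(ws, eye = header$eye,
                frame = matrix(unlist(header$frame), 3, 3))
}

#' Write / read a visual-space polygon as CSV (azimuth, elevation)
#'
#' @param map a [visual_space_map()].
#' @param path CSV path. The dilation is stored as a column constant.
#' @return `path`, invisibly.
#' @export
write_visual_space <- function(map, path) {
  stopifnot(inherits(map, "visual_space_map"))
  utils::write.csv(data.frame(azimuth = fmt_num(map$polygon[, 1]),
                              elevation = fmt_num(map$polygon[, 2]),
                              dilation = fmt_num(map$dilation)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visual_space
#' @export
read_visual_space <- function(path) {
  d <- utils::read.csv(path)
  visual_space_map(cbind(d$azimuth, d$elevation), dilation = d$dilation[1])
}

#' Write / read a cell cloud as CSV (x, y, z, layer, animal)
#'
#' @param cloud a `cell_cloud` data.frame from [gen_cell_cloud()] (any
#'   data.frame with those columns works).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_cloud <- function(cloud, path) {
  out <- data.frame(x = fmt_num(cloud$x), y = fmt_num(cloud$y),
                    z = fmt_num(cloud$z), layer = cloud$layer,
                    animal = cloud$animal)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_cloud
#' @export
read_cell_cloud <- function(path) {
  d <- utils::read.csv(path)
  attr(d, "projection_axes") <- c("x", "y")
  class(d) <- c("cell_cloud", "data.frame")
  d
}

#' Write / read a barrel map as a plain-text label matrix plus JSON metadata
#'
#' The raster is written as whitespace-separated integers (one matrix row
#' per line); pixel area and the barrel-id table go to `<path>.json`.
#'
#' @param map a [barrel_map()].
#' @param path text-matrix path; metadata goes to `paste0(path, ".json")`.
#' @param barrel_names optional named character vector mapping barrel id to
#'   a row/arc name (e.g. `c("1" = "A1")`), stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_barrel_map <- function(map, path, barrel_names = NULL) {
  stopifnot(inherits(map, "barrel_map"))
  utils::write.table(map$raster, path, row.names = FALSE, col.names = FALSE)
  ids <- sort(unique(as.vector(map$raster))); ids <- ids[ids > 0]
  jsonlite::write_json(
    list(pixel_area = map$pixel_area, barrel_ids = ids,
         barrel_names = as.list(barrel_names)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_barrel_map
#' @export
read_barrel_map <- function(path) {
  raster <- as.matrix(utils::read.table(path))
  dimnames(raster) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  barrel_map(raster, pixel_area = meta$pixel_area)
}
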