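# File contracts: camera/pose/pool/run configuration (YAML) and the CSV/JSON
# outputs shared between pipeline stages.

#' Write a centroid table
#'
#' CSV schema: `camera_id, frame, u, v, area, valid`.
#' @param track Centroid data.frame.
#' @param path Output path.
#' @export
write_centroid_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centroid table
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_centroid_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a trajectory table
#'
#' CSV schema: `frame, time_s, x_m, y_m, z_m, gap_m, valid, interpolated`.
#' @param traj Trajectory data.frame.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory table
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the swimming-ring table
#' @param rings Ring data.frame from [detect_rings()].
#' @param path Output path.
#' @export
write_rings_csv <- function(rings, path) {
  utils::write.csv(rings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the behavioural summary JSON
#' @param summary List from [analyze_trajectory()].
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

intrinsics_to_list <- function(intr) {
  list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
       width = intr$width, height = intr$height)
}

distortion_to_list <- function(d) {
  list(k1 = d$k1, k2 = d$k2, p1 = d$p1, p2 = d$p2, k3 = d$k3)
}

camera_from_list <- function(x) {
  intr <- do.call(camera_intrinsics, x$intrinsics)
  dist <- do.call(distortion_coefficients, x$distortion)
  pose <- NULL
  if (!is.null(x$pose))
    pose <- camera_pose(matrix(as.numeric(x$pose$rotation), 3, 3, byrow = TRUE),
                        as.numeric(x$pose$translation))
  pts <- NULL
  if (!is.null(x$calibration_points)) {
    pts <- list(
      world = do.call(rbind, lapply(x$calibration_points, function(p) as.numeric(p$world))),
      pixel = do.call(rbind, lapply(x$calibration_points, function(p) as.numeric(p$pixel))))
  }
  list(intrinsics = intr, distortion = dist, pose = pose,
       calibration_points = pts)
}

#' Read a camera definition file
#'
#' YAML with one entry per camera: `intrinsics` (fx, fy, cx, cy, width,
#' height), `distortion` (k1, k2, p1, p2, k3), optional `pose` (row-major
#' 9-number `rotation` plus 3-number `translation`), and optional
#' `calibration_points` (list of `{world: [x, y, z], pixel: [u, v]}`).
#'
#' @param path YAML path.
#' @return Named list of camera definitions.
#' @export
read_camera_config <- function(path) {
  lapply(yaml::read_yaml(path), camera_from_list)
}

#' Write a camera definition file
#'
#' @param cameras Named list of camera definitions (as from
#'   [read_camera_config()] or [default_camera_rig()]).
#' @param path Output YAML path.
#' @export
write_camera_config <- function(cameras, path) {
  out <- lapply(cameras, function(cam) {
    x <- list(intrinsics = intrinsics_to_list(cam$intrinsics),
              distortion = distortion_to_list(cam$distortion))
    if (!is.null(cam$pose))
      x$pose <- list(rotation = as.numeric(t(cam$pose$rotation)),
                     translation = as.numeric(cam$pose$translation))
    if (!is.null(cam$calibration_points)) {
      cp <- cam$calibration_points
      x$calibration_points <- lapply(seq_len(nrow(cp$world)), function(i)
        list(world = as.numeric(cp$world[i, ]),
             pixel = as.numeric(cp$pixel[i, ])))
    }
    x
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a pool geometry file
#'
#' YAML with `diameter`, `max_depth`, `shallow_max_depth`, optional
#' `deep_area_polygon` (list of [x, y]) and `regions` (named lists of
#' vertices).
#'
#' @param path YAML path.
#' @return A [pool_geometry()].
#' @export
read_pool_config <- function(path) {
  x <- yaml::read_yaml(path)
  poly <- if (!is.null(x$deep_area_polygon))
    do.call(rbind, lapply(x$deep_area_polygon, as.numeric)) else NULL
  regions <- lapply(x$regions %||% list(),
                    function(r) do.call(rbind, lapply(r, as.numeric)))
  pool_geometry(diameter = x$diameter %||% 21,
                max_depth = x$max_depth %||% 5,
                shallow_max_depth = x$shallow_max_depth %||% 1.4,
                deep_area_polygon = poly, regions = regions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
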