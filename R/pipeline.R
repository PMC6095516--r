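# End-to-end orchestration: calibrate both cameras, track both views,
# reconstruct the 3D trajectory, and produce the behavioural report.

log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run configuration
#'
#' Bundles everything a full run needs. The semi-automatic aspects of the
#' field workflow (filter parameters tuned by eye against the day's light)
#' are explicit configuration here; `preview = TRUE` makes the tracking
#' stage dump intermediate masks for manual tuning.
#'
#' @param frames_dir_a,frames_dir_b Per-camera directories of numbered PNG
#'   frames.
#' @param cameras Named list of two camera definitions (with poses after
#'   calibration).
#' @param pool A [pool_geometry()].
#' @param params A [segmentation_params()].
#' @param water A [water_model()].
#' @param fps Frames per second.
#' @param smoothing_sigma Pixel-smoothing sigma in frames.
#' @param max_gap Longest invalid run to interpolate, frames.
#' @param out_dir Output directory.
#' @param seed Seed for all randomness (RANSAC sampling).
#' @param frame_offset_b Frame-index offset of camera B relative to A, for
#'   streams started by a shared remote but not strictly aligned.
#' @param preview Write intermediate binary masks?
#' @return An object of class `run_config`.
#' @export
run_config <- function(frames_dir_a, frames_dir_b, cameras,
                       pool = pool_geometry(),
                       params = segmentation_params(),
                       water = water_model(), fps = 30,
                       smoothing_sigma = 32, max_gap = 30L,
                       out_dir = ".", seed = 1L, frame_offset_b = 0L,
                       preview = FALSE) {
  stopifnot(fps > 0)
  structure(list(frames_dir_a = frames_dir_a, frames_dir_b = frames_dir_b,
                 cameras = cameras, pool = pool, params = params,
                 water = water, fps = fps, smoothing_sigma = smoothing_sigma,
                 max_gap = max_gap, out_dir = out_dir, seed = as.integer(seed),
                 frame_offset_b = as.integer(frame_offset_b),
                 preview = preview),
            class = "run_config")
}

#' Calibrate both cameras from surveyed landmarks
#'
#' Estimates each camera's pose with RANSAC Perspective-n-Point from its
#' calibration points (at least 5 per camera, visible in that view), writes
#' the updated camera file and a per-point reprojection-error report, and
#' aborts naming the failing camera if either pose cannot be estimated.
#'
#' @param cameras Named list of camera definitions carrying
#'   `calibration_points` (`world` Nx3, `pixel` Nx2).
#' @param out_dir Output directory (camera file + report); `NULL` to skip
#'   writing.
#' @param seed RANSAC seed.
#' @param inlier_threshold_px RANSAC inlier threshold.
#' @return The camera list with `pose` filled in and a `calibration_report`
#'   attribute (data.frame: camera, point, residual_px, inlier).
#' @export
run_calibration <- function(cameras, out_dir = NULL, seed = 1L,
                            inlier_threshold_px = 5) {
  reports <- list()
  for (id in names(cameras)) {
    cam <- cameras[[id]]
    cp <- cam$calibration_points
    if (is.null(cp) || nrow(cp$world) < 5)
      stop("camera ", id, ": at least 5 calibration points are required")
    est <- tryCatch(
      estimate_pose_ransac(cp$world, cp$pixel, cam$intrinsics, cam$distortion,
                           seed = seed, inlier_threshold_px = inlier_threshold_px),
      error = function(e) stop("calibration failed for camera ", id, ": ",
                               conditionMessage(e)))
    cameras[[id]]$pose <- est$pose
    reports[[id]] <- data.frame(camera = id,
                                point = seq_along(est$residuals_px),
                                residual_px = est$residuals_px,
                                inlier = seq_along(est$residuals_px) %in% est$inliers)
    log_msg("camera ", id, ": ", length(est$inliers), "/",
            nrow(cp$world), " inliers, mean residual ",
            signif(mean(est$residuals_px[est$inliers]), 3), " px")
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_camera_config(cameras, file.path(out_dir, "cameras_calibrated.yaml"))
    utils::write.csv(report, file.path(out_dir, "calibration_report.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  attr(cameras, "calibration_report") <- report
  cameras
}

#' Track, reconstruct and analyse a full session
#'
#' Runs segmentation on both frame directories, smooths the pixel tracks,
#' triangulates with refraction, removes major outliers, interpolates short
#' gaps, and produces the behavioural report. All intermediates are written
#' to the output directory (centroid CSVs, trajectory CSV, rings CSV,
#' summary JSON), and the per-stage frame accounting is logged and returned,
#' so no frame is dropped silently.
#'
#' @param config A [run_config()] whose cameras carry poses.
#' @return List: `trajectory`, `summary`, `tracks` (per camera), `counts`
#'   (per-stage frame counts).
#' @export
run_tracking <- function(config) {
  for (id in names(config$cameras))
    if (is.null(config$cameras[[id]]$pose))
      stop("camera ", id, " has no pose; run calibration first")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_msg("segmenting camera A frames")
  ta <- track_frames(config$frames_dir_a, config$params, camera_id = "A")
  log_msg("segmenting camera B frames")
  tb <- track_frames(config$frames_dir_b, config$params, camera_id = "B")
  tb$frame <- tb$frame + config$frame_offset_b
  write_centroid_csv(ta, file.path(config$out_dir, "centroids_A.csv"))
  write_centroid_csv(tb, file.path(config$out_dir, "centroids_B.csv"))

  counts <- list(frames_detected_a = sum(ta$valid),
                 frames_detected_b = sum(tb$valid))
  cams <- config$cameras
  traj <- reconstruct_trajectory(ta, tb, cams[[1]], cams[[2]],
                                 water = config$water, fps = config$fps,
                                 sigma = config$smoothing_sigma,
                                 max_gap = config$max_gap)
  n_filtered <- if ("outlier_cause" %in% names(traj))
    sum(!is.na(traj$outlier_cause)) else 0L
  counts$frames_triangulated <- sum(traj$valid & !traj$interpolated) + n_filtered
  counts$frames_filtered <- n_filtered
  counts$frames_interpolated <- sum(traj$interpolated)
  counts$frames_valid_final <- sum(traj$valid)
  if (counts$frames_valid_final == 0) stop("zero triangulated frames")
  write_trajectory_csv(traj, file.path(config$out_dir, "trajectory.csv"))

  summary <- analyze_trajectory(traj, config$pool, config$fps)
  write_rings_csv(summary$rings, file.path(config$out_dir, "rings.csv"))
  write_summary_json(summary, file.path(config$out_dir, "summary.json"))
  log_msg("detected A/B: ", counts$frames_detected_a, "/",
          counts$frames_detected_b,
          "; triangulated: ", counts$frames_triangulated,
          "; filtered out: ", counts$frames_filtered,
          "; interpolated: ", counts$frames_interpolated,
          "; final valid: ", counts$frames_valid_final)
  list(trajectory = traj, summary = summary,
       tracks = list(A = ta, B = tb), counts = counts)
}

#' Simulate a synthetic session to disk
#'
#' Generates a ground-truth trajectory, projects it through the rig, and
#' writes the ground-truth CSV and per-camera pixel-track CSVs (and,
#' optionally, rendered PNG frames) under `out_dir`.
#'
#' @param config A [scene_config()].
#' @param segments Motion segments for [generate_trajectory()].
#' @param out_dir Output directory.
#' @param refraction,pixel_noise_sigma Passed to [project_truth()].
#' @param render Also render PNG frames?
#' @param appearance A [scene_appearance()] when rendering.
#' @return List: `ground_truth`, `tracks`, `frame_dirs` (or `NULL`).
#' @export
run_simulation <- function(config, segments, out_dir,
                           refraction = TRUE, pixel_noise_sigma = 0,
                           render = FALSE, appearance = scene_appearance()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_trajectory(config, segments)
  tracks <- project_truth(gt, config, refraction = refraction,
                          pixel_noise_sigma = pixel_noise_sigma)
  utils::write.csv(cbind(gt$positions, zone = gt$zones,
                         speed_mps = gt$speed_mps),
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_centroid_csv(tracks[[1]], file.path(out_dir, "track_A.csv"))
  write_centroid_csv(tracks[[2]], file.path(out_dir, "track_B.csv"))
  write_camera_config(config$cameras, file.path(out_dir, "cameras.yaml"))
  frame_dirs <- NULL
  if (render)
    frame_dirs <- render_frames(tracks, config, file.path(out_dir, "frames"),
                                appearance)
  list(ground_truth = gt, tracks = tracks, frame_dirs = frame_dirs)
}
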