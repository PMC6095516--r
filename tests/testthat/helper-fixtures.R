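# Shared fixtures, built in code.

# A distortion-free camera with the default intrinsics and an identity pose
# (camera at the world origin looking along +z).
identity_camera <- function() {
  list(intrinsics = camera_intrinsics(),
       distortion = distortion_coefficients(0, 0, 0, 0, 0),
       pose = camera_pose(diag(3), c(0, 0, 0)))
}

# Default synthetic rig + scene used across tests.
test_scene <- function(seed = 1L) scene_config(seed = seed)

# Quarter-resolution scene (320x180) for disk-heavy end-to-end tests; the
# geometry is identical, only the sensor is scaled.
small_scene <- function(seed = 1L) {
  intr <- camera_intrinsics(fx = 654.55 / 4, fy = 654.55 / 4,
                            cx = 319 / 2, cy = 179 / 2,
                            width = 320, height = 180)
  scene_config(cameras = default_camera_rig(intrinsics = intr), seed = seed)
}

# Appearance matched to the small sensor.
small_appearance <- function(...) {
  scene_appearance(blob_semi_axes = c(9, 4), ...)
}

# Segmentation parameters matched to the small sensor.
small_params <- function(...) {
  segmentation_params(adaptive_block = 31L, min_blob_area = 30L,
                      max_blob_area = 5000L, erosion_radius = 1L,
                      dilation_radius = 1L, ...)
}

# Rotation angle (rad) between two rotation matrices.
rotation_angle <- function(R1, R2) {
  ct <- (sum(diag(R1 %*% t(R2))) - 1) / 2
  acos(min(1, max(-1, ct)))
}

# Random landmark set spread through the pool volume, reproducible.
make_landmarks <- function(n, seed = 42) {
  set.seed(seed)
  cbind(runif(n, -8, 8), runif(n, -8, 8), runif(n, 0, 4))
}

# Build a minimal trajectory data.frame from a position matrix.
traj_from_positions <- function(p, fps = 30, valid = TRUE) {
  n <- nrow(p)
  data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fps,
             x_m = p[, 1], y_m = p[, 2], z_m = p[, 3], gap_m = 0,
             valid = rep_len(valid, n), interpolated = FALSE)
}

# Circle positions: n samples, radius r, turns full turns (closing sample
# included), constant depth.
circle_positions <- function(n, r, turns = 1, depth = 1, centre = c(0, 0),
                             direction = 1) {
  th <- direction * seq(0, 2 * pi * turns, length.out = n)
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th), depth)
}
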