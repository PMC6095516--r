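# Scene generator: trajectories, projections, rendering, determinism.

test_that("circular specs record their ring schedule by construction", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "circle", centre = c(0, 0),
                                           radius = 6, turns = 3,
                                           duration_s = 15, depth = 1)))
  expect_equal(nrow(gt$rings), 3L)
  expect_equal(gt$rings$end_frame - gt$rings$start_frame, rep(150, 3))
  expect_equal(nrow(gt$positions), 451L)
})

test_that("dwell jitter keeps speeds bounded", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "dwell",
                                           position = c(2, 3, 1),
                                           duration_s = 5, jitter_m = 0.05)))
  bound <- 2 * sqrt(3) * 0.05 * cfg$fps
  expect_true(all(gt$speed_mps[-1] <= bound + 1e-12))
})

test_that("dive depth oscillation alternates zones at the 1.4 m rule", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "dive", position = c(0, 0),
                                           depth_range = c(0.2, 3),
                                           period_s = 4, duration_s = 8)))
  z <- gt$positions$z_m
  expect_true(all(gt$zones[z > 1.4] == "Bottom"))
  expect_true(all(gt$zones[z <= 1.4] == "Deep Area"))
  expect_setequal(unique(gt$zones), c("Deep Area", "Bottom"))
})

test_that("trajectories escaping the pool are rejected", {
  cfg <- test_scene()
  expect_error(generate_trajectory(cfg, list(list(type = "circle",
                                                  centre = c(0, 0),
                                                  radius = 12, turns = 1,
                                                  duration_s = 5, depth = 1))),
               "pool bounds")
  expect_error(generate_trajectory(cfg, list(list(type = "dive",
                                                  position = c(0, 0),
                                                  depth_range = c(1, 7),
                                                  period_s = 4,
                                                  duration_s = 4))),
               "pool bounds")
})

test_that("generation and projection are deterministic under a fixed seed", {
  segs <- list(list(type = "dwell", position = c(1, 1, 2), duration_s = 2,
                    jitter_m = 0.02))
  g1 <- generate_trajectory(test_scene(seed = 5), segs)
  g2 <- generate_trajectory(test_scene(seed = 5), segs)
  expect_identical(g1, g2)
  t1 <- project_truth(g1, test_scene(seed = 5), pixel_noise_sigma = 2)
  t2 <- project_truth(g2, test_scene(seed = 5), pixel_noise_sigma = 2)
  expect_identical(t1, t2)
  t3 <- project_truth(g1, test_scene(seed = 6), pixel_noise_sigma = 2,
                      seed = 99L)
  expect_false(identical(t1$A$u, t3$A$u))
})

test_that("projection marks unusable observations invalid instead of failing", {
  cfg <- test_scene()
  # a rig aimed away from the pool: everything lands off-sensor or behind
  away <- list(
    A = list(intrinsics = camera_intrinsics(),
             distortion = distortion_coefficients(0, 0, 0, 0, 0),
             pose = look_at_pose(c(11, 0, -4), c(30, 0, -4)), centre = c(11, 0, -4)),
    B = list(intrinsics = camera_intrinsics(),
             distortion = distortion_coefficients(0, 0, 0, 0, 0),
             pose = look_at_pose(c(-11, 0, -4), c(-30, 0, -4)), centre = c(-11, 0, -4)))
  cfg_away <- scene_config(cameras = away, seed = 1)
  gt <- generate_trajectory(cfg_away, list(list(type = "dwell",
                                                position = c(0, 0, 2),
                                                duration_s = 1)))
  tk <- project_truth(gt, cfg_away)
  expect_false(any(tk$A$valid))
  expect_false(any(tk$B$valid))
})

test_that("refraction displaces projections and closes the loop at depth", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "dwell",
                                           position = c(3, 2, 3),
                                           duration_s = 0.1)))
  on <- project_truth(gt, cfg, refraction = TRUE)
  off <- project_truth(gt, cfg, refraction = FALSE)
  expect_gt(max(abs(on$A$u - off$A$u), abs(on$A$v - off$A$v)), 1)
  traj <- triangulate_tracks(on$A, on$B, cfg$cameras$A, cfg$cameras$B,
                             water = cfg$water, fps = cfg$fps)
  expect_lt(max(abs(traj$z_m - 3)), 0.05)
})

test_that("reconstruction error grows monotonically with pixel noise", {
  cfg <- test_scene(seed = 17)
  gt <- generate_trajectory(cfg, list(list(type = "circle", centre = c(0, 0),
                                           radius = 5, turns = 3,
                                           duration_s = 36, depth = 2.5)))
  med_err <- sapply(c(0, 1, 2, 4), function(sg) {
    tk <- project_truth(gt, cfg, refraction = TRUE, pixel_noise_sigma = sg)
    traj <- triangulate_tracks(tk$A, tk$B, cfg$cameras$A, cfg$cameras$B,
                               water = cfg$water, fps = cfg$fps)
    stats::median(sqrt((traj$x_m - gt$positions$x_m)^2 +
                       (traj$y_m - gt$positions$y_m)^2 +
                       (traj$z_m - gt$positions$z_m)^2), na.rm = TRUE)
  })
  expect_true(all(diff(med_err) > 0))
})

test_that("rendered frames are deterministic and degrade gracefully", {
  cfg <- test_scene(seed = 23)
  gt <- generate_trajectory(cfg, list(list(type = "dwell",
                                           position = c(0, 0, 1),
                                           duration_s = 0.1)))
  tk <- project_truth(gt, cfg)
  d1 <- file.path(tempdir(), "rf1"); d2 <- file.path(tempdir(), "rf2")
  render_frames(tk, cfg, d1, scene_appearance(noise_sigma = 3))
  render_frames(tk, cfg, d2, scene_appearance(noise_sigma = 3))
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(lapply(f1, function(f) readBin(f, "raw", 5e6)),
                   lapply(f2, function(f) readBin(f, "raw", 5e6)))
  # zero contrast: nothing to segment
  d3 <- file.path(tempdir(), "rf3")
  render_frames(tk, cfg, d3, scene_appearance(contrast = 0))
  ta <- track_frames(file.path(d3, "cam_A"), segmentation_params())
  expect_false(any(ta$valid))
  expect_error(render_frames(tk, cfg, tempdir(),
                             scene_appearance(blob_semi_axes = c(900, 500))),
               "larger than the frame")
  unlink(c(d1, d2, d3), recursive = TRUE)
})
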