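# Zones, speeds, rings, regions.

test_that("speeds are displacement over the frame interval", {
  p <- cbind(seq(0, 0.5, by = 0.1), 0, 1)   # 0.1 m per frame
  sp <- compute_speeds(traj_from_positions(p), fps = 30)
  expect_equal(sp$speed_mps[-1], rep(3, 5))
  expect_true(is.na(sp$speed_mps[1]))
  stat <- compute_speeds(traj_from_positions(matrix(1, 10, 3)), fps = 30)
  expect_equal(stat$speed_mps[-1], rep(0, 9))
  expect_error(compute_speeds(traj_from_positions(matrix(0, 5, 3),
                                                  valid = FALSE)),
               "consecutive")
})

test_that("circular motion speed matches the chord-length formula", {
  r <- 6; omega <- 0.05; fps <- 30; n <- 200
  th <- omega * (0:(n - 1))
  p <- cbind(r * cos(th), r * sin(th), 2)
  sp <- compute_speeds(traj_from_positions(p), fps = fps)
  chord <- 2 * r * sin(omega / 2) * fps
  expect_equal(sp$speed_mps[-1], rep(chord, n - 1), tolerance = 1e-9)
})

test_that("frame interval conversion matches published values", {
  expect_equal(frame_interval_ms(30), 33.33)
  expect_equal(frame_interval_ms(1000), 1)
  expect_equal(frame_interval_ms(25), 40)
  expect_error(frame_interval_ms(0), "positive")
})

test_that("speed category bounds are equal-width thirds of the range", {
  expect_equal(speed_category_bounds(5.1), c(1.7, 3.4))
  expect_equal(speed_category_bounds(3), c(1, 2))
  expect_equal(speed_category_bounds(9), c(3, 6))
  expect_error(speed_category_bounds(0), "positive")
  # data mode: empirical tertiles instead
  v <- c(rep(1, 50), rep(2, 25), rep(6, 25))
  b <- speed_category_bounds(6, speeds = v, mode = "data")
  expect_equal(b, as.numeric(stats::quantile(v, c(1/3, 2/3), names = FALSE)))
})

test_that("speed-time summary partitions all valid frames", {
  mk <- function(sp) {
    out <- data.frame(frame = seq_along(sp) - 1, speed_mps = sp,
                      valid = TRUE, interpolated = FALSE)
    attr(out, "max_speed_mps") <- max(sp)
    out
  }
  one <- speed_time_summary(mk(rep(0.5, 900)), fps = 30,
                            bounds = c(1.7, 3.4))
  expect_equal(one$percent[one$category == "low"], 100)
  expect_equal(one$minutes[one$category == "low"], 0.5)
  thirds <- speed_time_summary(mk(c(rep(1, 100), rep(2.5, 100), rep(4, 100))),
                               fps = 30, bounds = c(1.7, 3.4))
  expect_equal(thirds$percent, rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(thirds$percent), 100, tolerance = 1e-9)
})

test_that("zone labels follow depth first, then the deep footprint", {
  pool <- pool_geometry()
  expect_equal(classify_zone(0, 0, 3, pool), "Bottom")
  expect_equal(classify_zone(9.5, 0, 3, pool), "Bottom")  # depth wins anywhere
  expect_equal(classify_zone(0, 0, 0.2, pool), "Deep Area")
  expect_equal(classify_zone(9.5, 0, 0.2, pool), "Shallow Area")
  expect_true(is.na(classify_zone(NA, 0, 1, pool)))
  # exactly one label for any in-pool position
  set.seed(2)
  x <- runif(500, -10, 10); y <- runif(500, -10, 10); z <- runif(500, 0, 5)
  labs <- classify_zone(x, y, z, pool)
  expect_true(all(labs %in% c("Deep Area", "Shallow Area", "Bottom")))
})

test_that("occupancy minutes and percentages are consistent", {
  p <- cbind(0, 0, rep(0.5, 1800))        # centre, shallow depth -> Deep Area
  occ <- occupancy_summary(traj_from_positions(p), pool_geometry(), fps = 30)
  expect_equal(occ$minutes[occ$zone == "Deep Area"], 1)
  expect_equal(occ$percent[occ$zone == "Deep Area"], 100)
  expect_equal(sum(occ$percent), 100, tolerance = 1e-9)
  # frames-to-seconds conversion used for session reporting
  expect_equal(round(469 / 30, 2), 15.63)
  occ469 <- occupancy_summary(traj_from_positions(cbind(0, 0, rep(0.5, 469))),
                              pool_geometry(), fps = 30)
  expect_equal(round(sum(occ469$minutes) * 60, 2), 15.63)
})

test_that("a scripted zone schedule is recovered exactly", {
  # 300 frames Deep (z 0.5 centre), 150 Bottom (z 3), 50 Shallow (edge z 0.5)
  p <- rbind(cbind(0, 0, rep(0.5, 300)),
             cbind(0, 0, rep(3, 150)),
             cbind(9.5, 0, rep(0.5, 50)))
  occ <- occupancy_summary(traj_from_positions(p), pool_geometry(), fps = 30)
  expect_equal(occ$frames, c(300L, 50L, 150L))  # Deep, Shallow, Bottom order
  expect_equal(occ$percent, c(60, 10, 30))
})

test_that("complete circuits are detected with exact counts and spans", {
  pool <- pool_geometry()
  p <- circle_positions(301, r = 6, turns = 2, depth = 1)
  rings <- detect_rings(traj_from_positions(p), pool, fps = 30)
  expect_equal(nrow(rings), 2L)
  expect_equal(rings$duration_frames, c(150, 150))
  # half-turn back-and-forth arc never accumulates 2*pi
  th <- c(seq(0, pi, length.out = 100), seq(pi, 0, length.out = 100))
  arc <- cbind(6 * cos(th), 6 * sin(th), 1)
  expect_equal(nrow(detect_rings(traj_from_positions(arc), pool, fps = 30)), 0L)
  # jitter does not change the count
  set.seed(9)
  pj <- p + cbind(rnorm(301, 0, 0.1), rnorm(301, 0, 0.1), 0)
  expect_equal(nrow(detect_rings(traj_from_positions(pj), pool, fps = 30)), 2L)
  # tight pivoting below the radius floor is rejected
  tiny <- circle_positions(100, r = 0.5, turns = 2, depth = 1)
  expect_equal(nrow(detect_rings(traj_from_positions(tiny), pool, fps = 30)), 0L)
})

test_that("ring detection is direction-agnostic and reversal-invariant", {
  pool <- pool_geometry()
  for (k in 1:4) {
    p <- circle_positions(k * 120 + 1, r = 5, turns = k, depth = 2,
                          direction = if (k %% 2) 1 else -1)
    rings <- detect_rings(traj_from_positions(p), pool, fps = 30)
    expect_equal(nrow(rings), k)
    rev_rings <- detect_rings(traj_from_positions(p[nrow(p):1, ]), pool,
                              fps = 30)
    expect_equal(nrow(rev_rings), k)
    expect_equal(sort(rev_rings$duration_frames), sort(rings$duration_frames))
  }
})

test_that("ring metrics reproduce closed-form circle geometry", {
  fps <- 30
  # 469-frame ring: duration in seconds as published for the mean ring
  p <- circle_positions(470, r = 6, turns = 1, depth = 1)
  m <- ring_metrics(traj_from_positions(p, fps = fps), 0, 469, fps = fps)
  expect_equal(round(m$duration_s, 2), 15.63)
  expect_equal(m$duration_frames, 469)
  # closed circle: start-end distance ~ 0, path ~ circumference
  expect_lt(m$start_end_distance_m, 1e-9)
  expect_equal(m$path_length_m, 2 * pi * 6, tolerance = 1e-3)
  # chord-sum closed form: r = 5 m, 100 samples per turn
  p2 <- circle_positions(101, r = 5, turns = 1, depth = 1)
  m2 <- ring_metrics(traj_from_positions(p2, fps = fps), 0, 100, fps = fps)
  expect_equal(m2$path_length_m, 100 * 2 * 5 * sin(pi / 100), tolerance = 1e-9)
  expect_gte(m2$path_length_m, m2$start_end_distance_m)
  expect_equal(m2$mean_radius_m, 5, tolerance = 1e-9)
})

test_that("region time reflects the scripted schedule", {
  square <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  inside <- cbind(0, 0, rep(1, 75))
  outside <- cbind(5, 5, rep(1, 225))
  tj <- traj_from_positions(rbind(inside, outside))
  rt <- region_time(tj, square, fps = 30)
  expect_equal(rt$percent, 25)
  expect_equal(rt$frames, 75)
  expect_equal(region_time(traj_from_positions(outside), square, 30)$percent, 0)
  expect_equal(region_time(traj_from_positions(inside), square, 30)$percent, 100)
  expect_error(region_time(tj, rbind(c(0, 0), c(1, 1)), 30), "degenerate")
})

test_that("the bundled report is internally consistent", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "circle", centre = c(0, 0),
                                           radius = 5, turns = 3,
                                           duration_s = 15, depth = 2)))
  rep <- analyze_trajectory(gt$positions, cfg$pool, cfg$fps)
  expect_equal(nrow(rep$rings), 3L)
  expect_equal(sum(rep$occupancy$percent), 100, tolerance = 1e-9)
  expect_equal(sum(rep$speed$summary$percent), 100, tolerance = 1e-9)
  expect_equal(rep$speed$bounds_mps[2], 2 * rep$speed$max_speed_mps / 3,
               tolerance = 1e-12)
})
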