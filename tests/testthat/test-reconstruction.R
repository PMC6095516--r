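# Smoothing, refraction, triangulation, outlier filtering.

test_that("Gaussian smoothing preserves constants and interior ramps", {
  tr <- data.frame(frame = 0:199, u = 7, v = -3, valid = TRUE)
  s <- smooth_pixel_track(tr, 32)
  expect_equal(s$u, rep(7, 200))
  expect_equal(s$v, rep(-3, 200))
  # linear ramp: unchanged everywhere (trend-preserving boundaries)
  n <- 500
  tr2 <- data.frame(frame = 0:(n - 1), u = as.numeric(0:(n - 1)), v = 0,
                    valid = TRUE)
  s2 <- smooth_pixel_track(tr2, 32)
  expect_lt(max(abs(s2$u - tr2$u)), 1e-9)
})

test_that("impulse response is the sampled, normalized Gaussian kernel", {
  sigma <- 32
  n <- 1100
  x <- rep(0, n); x[551] <- 1
  tr <- data.frame(frame = 0:(n - 1), u = x, v = 0, valid = TRUE)
  s <- smooth_pixel_track(tr, sigma)
  # independent kernel evaluation
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(sum(s$u), 1, tolerance = 1e-9)
  expect_equal(s$u[(551 - r):(551 + r)], k, tolerance = 1e-12)
})

test_that("smoothing respects detection gaps and local extremes", {
  # two valid runs separated by a gap: each run smoothed as if alone
  u <- c(rep(10, 60), rep(NA, 5), rep(50, 60))
  tr <- data.frame(frame = 0:124, u = u, v = 0, valid = !is.na(u))
  s <- smooth_pixel_track(tr, 8)
  expect_equal(s$u[1:60], rep(10, 60))
  expect_equal(s$u[66:125], rep(50, 60))
  # interior samples never leave the [min, max] of their 8-sigma
  # neighbourhood (boundary samples may, by trend continuation)
  set.seed(12)
  x <- cumsum(rnorm(400))
  tr2 <- data.frame(frame = 0:399, u = x, v = 0, valid = TRUE)
  s2 <- smooth_pixel_track(tr2, 5)
  w <- 8 * 5
  for (i in seq(w + 1, 400 - w, by = 7)) {
    nb <- x[max(1, i - w):min(400, i + w)]
    expect_gte(s2$u[i], min(nb) - 1e-9)
    expect_lte(s2$u[i], max(nb) + 1e-9)
  }
})

test_that("refraction bends rays toward the vertical by Snell's law", {
  w <- water_model(1.4)
  # normal incidence: direction unchanged
  r <- refract_ray(ray(c(1, 2, -4), c(0, 0, 1)), w)
  expect_equal(r$direction, c(0, 0, 1))
  expect_equal(r$origin, c(1, 2, 0))
  # index 1: direction unchanged, origin moved to the surface
  r1 <- refract_ray(ray(c(0, 0, -2), c(1, 0, 1)), water_model(1))
  expect_equal(r1$direction, c(1, 0, 1) / sqrt(2))
  expect_equal(r1$origin, c(2, 0, 0))
  # 45 degrees: underwater angle asin(sin(45)/1.4), azimuth preserved
  r45 <- refract_ray(ray(c(0, 0, -1), c(1, 0, 1)), w)
  th_w <- asin(sin(pi / 4) / 1.4)
  expect_equal(r45$direction, c(sin(th_w), 0, cos(th_w)))
  expect_error(refract_ray(ray(c(0, 0, -1), c(1, 0, 0)), w), "parallel")
  expect_error(refract_ray(ray(c(0, 0, 1), c(0, 0, 1)), w), "above")
})

test_that("triangulation recovers exact intersections and flags parallels", {
  P <- c(1, 2, -1)   # above water, no refraction branch
  o1 <- c(10, 0, -4); o2 <- c(-10, 0, -4)
  tri <- triangulate(ray(o1, P - o1), ray(o2, P - o2))
  expect_equal(tri$position, P, tolerance = 1e-9)
  expect_equal(tri$gap, 0, tolerance = 1e-12)
  expect_error(triangulate(ray(o1, c(0, 0, 1)), ray(o2, c(0, 0, 1))),
               "parallel")
})

test_that("skew-ray midpoint matches brute-force closest-approach search", {
  set.seed(8)
  for (i in 1:10) {
    o1 <- runif(3, -5, 5); o2 <- runif(3, -5, 5)
    d1 <- rnorm(3); d2 <- rnorm(3)
    d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
    if (abs(sum(d1 * d2)) > 0.99) next
    # independent oracle: numeric minimization over the two line parameters
    f <- function(st) sum((o1 + st[1] * d1 - o2 - st[2] * d2)^2)
    opt <- stats::optim(c(0, 0), f, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 1000))
    mid_oracle <- (o1 + opt$par[1] * d1 + o2 + opt$par[2] * d2) / 2
    tri <- triangulate(ray(o1, d1), ray(o2, d2), water = NULL)
    expect_equal(tri$position, mid_oracle, tolerance = 1e-7)
    expect_equal(tri$gap, sqrt(f(opt$par)), tolerance = 1e-7)
  }
})

test_that("underwater midpoints trigger the refraction branch", {
  cfg <- test_scene()
  P <- c(2, -1, 3)
  ctrA <- camera_centre(cfg$cameras$A$pose)
  ctrB <- camera_centre(cfg$cameras$B$pose)
  SA <- dtrack3d:::refraction_surface_point(ctrA, P, cfg$water)
  SB <- dtrack3d:::refraction_surface_point(ctrB, P, cfg$water)
  tri <- triangulate(ray(ctrA, SA - ctrA), ray(ctrB, SB - ctrB),
                     water = cfg$water)
  expect_equal(tri$position, P, tolerance = 1e-6)
})

test_that("outer-fence filtering removes the planted spike only", {
  # hand case: series 10,11,12,11,10,12,11,10,12 with one frame at 1000
  z <- c(10, 11, 12, 11, 1000, 12, 11, 10, 12)
  tj <- traj_from_positions(cbind(z, 0, 0))
  f <- filter_outliers(tj)
  # hand computation, type-7 quantiles of the x series:
  # sorted 10,10,11,11,11,12,12,12,1000; Q1 = 11, Q3 = 12, IQR = 1,
  # outer fences (8, 15): only the 1000 frame is outside
  expect_equal(which(!f$valid), 5L)
  expect_equal(f$outlier_cause[5], "coordinate")
  expect_true(all(f$valid[-5]))
  # all-constant trajectory: IQR 0, fences collapse, equal values retained
  tc <- traj_from_positions(matrix(1, 20, 3))
  expect_true(all(filter_outliers(tc)$valid))
})

test_that("in-fence jitter is untouched and the filter is idempotent", {
  set.seed(4)
  n <- 120
  p <- cbind(5 * cos(seq(0, 4 * pi, length.out = n)) + rnorm(n, 0, 0.05),
             5 * sin(seq(0, 4 * pi, length.out = n)) + rnorm(n, 0, 0.05),
             2 + rnorm(n, 0, 0.05))
  tj <- traj_from_positions(p)
  expect_true(all(filter_outliers(tj)$valid))
  # spike it
  tj2 <- tj
  tj2$z_m[60] <- 40
  f1 <- filter_outliers(tj2)
  expect_false(f1$valid[60])
  f2 <- filter_outliers(f1)
  expect_identical(f1$valid, f2$valid)
  expect_equal(f1, f2)
})

test_that("the filter warns and passes through short trajectories", {
  tj <- traj_from_positions(matrix(rnorm(15), 5, 3))
  expect_warning(out <- filter_outliers(tj), "fewer than 8")
  expect_identical(out$valid, tj$valid)
})

test_that("short gaps are interpolated and flagged, long gaps left invalid", {
  p <- cbind(seq(0, 10, length.out = 101), 0, 1)
  tj <- traj_from_positions(p)
  tj$valid[11:13] <- FALSE              # 3-frame gap
  tj$valid[41:80] <- FALSE              # 40-frame gap
  out <- interpolate_gaps(tj, max_gap = 30)
  expect_true(all(out$valid[11:13]))
  expect_true(all(out$interpolated[11:13]))
  expect_equal(out$x_m[11:13], p[11:13, 1], tolerance = 1e-12)
  expect_false(any(out$valid[41:80]))
})

test_that("noise-free end-to-end reconstruction is exact to the millimetre", {
  cfg <- test_scene()
  gt <- generate_trajectory(cfg, list(list(type = "circle", centre = c(0, 0),
                                           radius = 5, turns = 1,
                                           duration_s = 5, depth = c(2, 4.5))))
  tk <- project_truth(gt, cfg, refraction = FALSE)
  traj <- triangulate_tracks(tk$A, tk$B, cfg$cameras$A, cfg$cameras$B,
                             water = NULL, fps = cfg$fps)
  err <- sqrt((traj$x_m - gt$positions$x_m)^2 +
              (traj$y_m - gt$positions$y_m)^2 +
              (traj$z_m - gt$positions$z_m)^2)
  expect_lt(stats::median(err, na.rm = TRUE), 0.01)
  # refraction on: depth recovered
  tkr <- project_truth(gt, cfg, refraction = TRUE)
  trajr <- triangulate_tracks(tkr$A, tkr$B, cfg$cameras$A, cfg$cameras$B,
                              water = cfg$water, fps = cfg$fps)
  expect_lt(max(abs(trajr$z_m - gt$positions$z_m), na.rm = TRUE), 0.05)
})
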