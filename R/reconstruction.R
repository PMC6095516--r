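# Paired pixel tracks -> smoothed, outlier-filtered 3D trajectory.
#
# World frame: origin at the pool centre on the water surface, z positive
# downward (z is depth in metres). Cameras sit above the water at z < 0.

#' Air-water interface model
#'
#' Flat interface at z = 0 with a single effective refraction index. The
#' default 1.4 is the value calibrated against known in-pool distances in the
#' original deployment (kept rather than the textbook 1.33, as the effective
#' index also absorbs residual camera-model error); it is configurable.
#'
#' @param refraction_index Water/air refraction ratio, >= 1.
#' @return An object of class `water_model`.
#' @export
water_model <- function(refraction_index = 1.4) {
  stopifnot(refraction_index >= 1)
  structure(list(surface_z = 0, refraction_index = refraction_index),
            class = "water_model")
}

# Gaussian kernel truncated at 4 sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Value of the series at a virtual index under iterated odd (point-mirrored)
# reflection about the end points: v(2 - j) = 2 x[1] - v(j) and
# v(2n - j) = 2 x[n] - v(j). Odd reflection continues the local trend, so
# smoothing is exact for affine signals up to and including the boundary
# samples (an even mirror would flatten every trend at the ends).
odd_reflect_value <- function(x, j) {
  n <- length(x)
  a <- 1; b <- 0
  while (j < 1L || j > n) {
    if (j < 1L) { b <- b + a * 2 * x[1]; a <- -a; j <- 2L - j }
    else        { b <- b + a * 2 * x[n]; a <- -a; j <- 2L * n - j }
  }
  a * x[j] + b
}

gaussian_smooth_series <- function(x, sigma) {
  n <- length(x)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L || n == 0L || n == 1L) return(x)
  left <- vapply((1L - r):0L, function(j) odd_reflect_value(x, j), numeric(1))
  right <- vapply((n + 1L):(n + r), function(j) odd_reflect_value(x, j),
                  numeric(1))
  stats::convolve(c(left, x, right), rev(k), type = "filter")
}

#' Smooth a pixel track with a Gaussian filter
#'
#' Convolves the u and v centroid series with a Gaussian kernel (truncated at
#' 4 sigma), applied independently to each contiguous run of valid frames so
#' detection gaps do not bleed across. Boundaries are handled by odd
#' (point-mirrored) reflection, which continues the local trend: an even
#' mirror would flatten the ends of every moving track, dragging the first
#' and last ~sigma frames of a swim towards a standstill. The default sigma
#' of 32 frames (about one second at 30 fps) suppresses centroid jitter from
#' segmentation noise.
#'
#' @param track Centroid data.frame with columns `frame`, `u`, `v`, `valid`.
#' @param sigma Kernel standard deviation in frames (>= 0).
#' @return The track with smoothed `u`, `v`.
#' @export
smooth_pixel_track <- function(track, sigma = 32) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(track)
  runs <- rle(track$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    i <- starts[j]:ends[j]
    track$u[i] <- gaussian_smooth_series(track$u[i], sigma)
    track$v[i] <- gaussian_smooth_series(track$v[i], sigma)
  }
  track
}

#' Refract a ray at the water surface
#'
#' Continues a downward-travelling air ray into the water: the new origin is
#' the intersection with the surface plane z = 0, and the direction is bent
#' toward the vertical by Snell's law, `sin(theta_air) = n * sin(theta_water)`,
#' with the horizontal azimuth preserved.
#'
#' @param r A [ray()] with origin above the surface (z < 0) and direction
#'   pointing downward (positive z component).
#' @param water A [water_model()].
#' @return The underwater [ray()].
#' @export
refract_ray <- function(r, water = water_model()) {
  if (r$origin[3] > water$surface_z + 1e-12)
    stop("ray origin must be above the water surface")
  if (r$direction[3] <= 1e-12)
    stop("ray parallel to or pointing away from the surface")
  t_hit <- (water$surface_z - r$origin[3]) / r$direction[3]
  hit <- r$origin + t_hit * r$direction
  n <- water$refraction_index
  sin_air <- sqrt(r$direction[1]^2 + r$direction[2]^2)  # direction is unit
  sin_w <- sin_air / n
  cos_w <- sqrt(1 - sin_w^2)
  if (sin_air < 1e-15) return(ray(hit, c(0, 0, 1)))     # normal incidence
  az <- c(r$direction[1], r$direction[2]) / sin_air
  ray(hit, c(az * sin_w, cos_w))
}

# Closest points between two lines o1 + s d1, o2 + t d2 (d unit).
line_closest_points <- function(o1, d1, o2, d2) {
  w0 <- o1 - o2
  b <- sum(d1 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  denom <- 1 - b^2
  s <- (b * e - d) / denom
  t <- (e - b * d) / denom
  list(p1 = o1 + s * d1, p2 = o2 + t * d2, denom = denom)
}

#' Triangulate a 3D position from two viewing rays
#'
#' The two back-projected rays are generically skew, so the "intersection" is
#' realized as the midpoint of their common perpendicular; the length of that
#' segment is returned as a gap (quality score). If the unrefracted midpoint
#' falls below the water surface, both rays are refracted at the surface
#' ([refract_ray()]) and the midpoint is recomputed on the underwater
#' segments.
#'
#' @param ray_a,ray_b [ray()]s from the two camera centres.
#' @param water A [water_model()], or `NULL` to disable refraction.
#' @param min_angle_deg Rays closer to parallel than this angle are rejected.
#' @return List with `position` (length-3, metres) and `gap` (metres).
#' @export
triangulate <- function(ray_a, ray_b, water = water_model(),
                        min_angle_deg = 0.5) {
  min_denom <- sin(min_angle_deg * pi / 180)^2
  cp <- line_closest_points(ray_a$origin, ray_a$direction,
                            ray_b$origin, ray_b$direction)
  if (cp$denom < min_denom) stop("rays are near-parallel; cannot triangulate")
  mid <- (cp$p1 + cp$p2) / 2
  if (!is.null(water) && mid[3] > water$surface_z &&
      ray_a$direction[3] > 1e-12 && ray_b$direction[3] > 1e-12 &&
      ray_a$origin[3] < water$surface_z && ray_b$origin[3] < water$surface_z) {
    ra <- refract_ray(ray_a, water); rb <- refract_ray(ray_b, water)
    cp <- line_closest_points(ra$origin, ra$direction, rb$origin, rb$direction)
    if (cp$denom < min_denom) stop("refracted rays are near-parallel")
    mid <- (cp$p1 + cp$p2) / 2
  }
  list(position = mid, gap = sqrt(sum((cp$p1 - cp$p2)^2)))
}

#' Triangulate paired pixel tracks into a 3D trajectory
#'
#' For every frame with a valid centroid in both cameras, back-projects both
#' pixels to rays and triangulates (with refraction when the point is
#' underwater). Frames missing in either camera, or whose rays are
#' near-parallel, are invalid.
#'
#' @param track_a,track_b Centroid data.frames (`frame`, `u`, `v`, `valid`),
#'   covering the same frame range.
#' @param cam_a,cam_b Camera definitions: lists with `intrinsics`,
#'   `distortion`, `pose`.
#' @param water A [water_model()] or `NULL`.
#' @param fps Frames per second (> 0, default 30).
#' @return Trajectory data.frame: `frame`, `time_s`, `x_m`, `y_m`, `z_m`,
#'   `gap_m`, `valid`, `interpolated`.
#' @export
triangulate_tracks <- function(track_a, track_b, cam_a, cam_b,
                               water = water_model(), fps = 30) {
  stopifnot(fps > 0)
  frames <- sort(union(track_a$frame, track_b$frame))
  ia <- match(frames, track_a$frame); ib <- match(frames, track_b$frame)
  n <- length(frames)
  out <- data.frame(frame = frames, time_s = frames / fps,
                    x_m = NA_real_, y_m = NA_real_, z_m = NA_real_,
                    gap_m = NA_real_, valid = FALSE, interpolated = FALSE)
  for (i in seq_len(n)) {
    if (is.na(ia[i]) || is.na(ib[i])) next
    if (!track_a$valid[ia[i]] || !track_b$valid[ib[i]]) next
    res <- tryCatch({
      ra <- pixel_to_ray(c(track_a$u[ia[i]], track_a$v[ia[i]]),
                         cam_a$intrinsics, cam_a$distortion, cam_a$pose)
      rb <- pixel_to_ray(c(track_b$u[ib[i]], track_b$v[ib[i]]),
                         cam_b$intrinsics, cam_b$distortion, cam_b$pose)
      triangulate(ra, rb, water)
    }, error = function(e) NULL)
    if (is.null(res)) next
    out$x_m[i] <- res$position[1]; out$y_m[i] <- res$position[2]
    out$z_m[i] <- res$position[3]; out$gap_m[i] <- res$gap
    out$valid[i] <- TRUE
  }
  out
}

tukey_outer_outliers <- function(x, fence_factor = 3, one_sided = FALSE) {
  if (all(is.na(x))) return(rep(FALSE, length(x)))
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - fence_factor * iqr
  hi <- q[2] + fence_factor * iqr
  !is.na(x) & (x > hi | (!one_sided & x < lo))
}

#' Discard major trajectory outliers (Tukey outer fences)
#'
#' For each coordinate series (x, y, z) and for the per-frame displacement
#' series, computes the quartiles (linear interpolation between order
#' statistics), the interquartile range, and the outer fences
#' `Q1 - 3 IQR` / `Q3 + 3 IQR`. Frames with any value beyond an outer fence
#' -- the major outliers -- are invalidated; everything else is untouched, so
#' jitter inside the fences survives. The per-frame cause is recorded in an
#' `outlier_cause` column (`"coordinate"` or `"displacement"`).
#'
#' Coordinates are tested against both fences. The displacement series is
#' tested only against the upper fence -- a small displacement is ordinary
#' behaviour (the animal may simply be still) -- and a frame is flagged only
#' when both its incoming and outgoing displacements are beyond it: a
#' tracking glitch teleports the detection away *and* back, while the
#' innocent frame after a glitch shares just the return jump.
#'
#' @param traj Trajectory data.frame as from [triangulate_tracks()].
#' @param fence_factor Fence multiplier; 3 is the outer (major-outlier)
#'   fence, 1.5 would be the inner fence.
#' @return The trajectory with outlying frames invalidated.
#' @export
filter_outliers <- function(traj, fence_factor = 3) {
  v <- which(traj$valid)
  if (length(v) < 8) {
    warning("fewer than 8 valid positions; outlier filter skipped")
    return(traj)
  }
  bad_coord <- tukey_outer_outliers(traj$x_m[v], fence_factor) |
    tukey_outer_outliers(traj$y_m[v], fence_factor) |
    tukey_outer_outliers(traj$z_m[v], fence_factor)
  # displacement series: a tracking glitch teleports the detection away and
  # back, so a glitched frame has an outlying jump on BOTH sides; its
  # innocent neighbours share only one. Flag interior frames whose incoming
  # and outgoing displacements both exceed the upper outer fence.
  p <- cbind(traj$x_m[v], traj$y_m[v], traj$z_m[v])
  steps <- diff(traj$frame[v])
  disp <- sqrt(rowSums(diff(p)^2))
  disp[steps != 1] <- NA                       # only truly consecutive frames
  out_hi <- tukey_outer_outliers(disp, fence_factor, one_sided = TRUE)
  bad_disp <- c(FALSE, out_hi) & c(out_hi, FALSE)
  bad <- bad_coord | bad_disp
  if (!"outlier_cause" %in% names(traj)) traj$outlier_cause <- NA_character_
  traj$outlier_cause[v[bad_coord]] <- "coordinate"
  traj$outlier_cause[v[bad_disp & !bad_coord]] <- "displacement"
  idx <- v[bad]
  traj$valid[idx] <- FALSE
  traj$x_m[idx] <- NA_real_; traj$y_m[idx] <- NA_real_; traj$z_m[idx] <- NA_real_
  if ("gap_m" %in% names(traj)) traj$gap_m[idx] <- NA_real_
  traj
}

#' Fill short detection gaps by linear interpolation
#'
#' Runs of up to `max_gap` consecutive invalid frames flanked by valid ones
#' are filled by linear interpolation of x, y, z over time and flagged in the
#' `interpolated` column; longer gaps stay invalid.
#'
#' @param traj Trajectory data.frame.
#' @param max_gap Longest gap (frames) to fill; default 30 (one second at
#'   30 fps).
#' @return The trajectory with short gaps filled.
#' @export
interpolate_gaps <- function(traj, max_gap = 30L) {
  v <- which(traj$valid)
  if (length(v) < 2) return(traj)
  for (k in seq_len(length(v) - 1L)) {
    gap <- v[k + 1L] - v[k] - 1L
    if (gap < 1L || gap > max_gap) next
    i <- (v[k] + 1L):(v[k + 1L] - 1L)
    w <- (traj$frame[i] - traj$frame[v[k]]) /
      (traj$frame[v[k + 1L]] - traj$frame[v[k]])
    for (col in c("x_m", "y_m", "z_m"))
      traj[[col]][i] <- traj[[col]][v[k]] * (1 - w) + traj[[col]][v[k + 1L]] * w
    traj$valid[i] <- TRUE
    traj$interpolated[i] <- TRUE
  }
  traj
}

#' Full reconstruction chain: pixel tracks to filtered 3D trajectory
#'
#' Gaussian pixel smoothing, two-ray triangulation with refraction, Tukey
#' outer-fence outlier removal, and short-gap interpolation, in that order.
#'
#' @inheritParams triangulate_tracks
#' @param sigma Pixel-smoothing sigma in frames (default 32).
#' @param max_gap Longest invalid run to interpolate (default 30 frames).
#' @return Trajectory data.frame.
#' @export
reconstruct_trajectory <- function(track_a, track_b, cam_a, cam_b,
                                   water = water_model(), fps = 30,
                                   sigma = 32, max_gap = 30L) {
  ta <- smooth_pixel_track(track_a, sigma)
  tb <- smooth_pixel_track(track_b, sigma)
  traj <- triangulate_tracks(ta, tb, cam_a, cam_b, water, fps)
  traj <- filter_outliers(traj)
  interpolate_gaps(traj, max_gap)
}
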