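# Synthetic scene generation: ground-truth trajectories, projection through
# the two-camera rig (optionally refracted and noisy), and simple frame
# rendering, so the whole pipeline can be exercised without real footage.

#' Default two-camera rig for a circular pool
#'
#' Two cameras on opposite sides of the pool, 4 m above the water at a
#' horizontal radius just outside the wall, pitched to view the pool volume.
#' Intrinsics default to the calibrated 1280x720 values; the default
#' synthetic distortion is a mild radial model (k1 = -0.12, k2 = 0.02) that
#' is invertible over the whole sensor.
#'
#' @param pool A [pool_geometry()].
#' @param height Camera height above the water surface (m).
#' @param radius Horizontal distance of the cameras from the pool centre (m);
#'   default: pool radius + 0.5.
#' @param intrinsics,distortion Shared camera internals.
#' @param aim Point the optical axes pass through; default `(0, 0, 2)`, the
#'   mid-depth pool centre.
#' @return List of two camera definitions (`intrinsics`, `distortion`,
#'   `pose`, `centre`).
#' @export
default_camera_rig <- function(pool = pool_geometry(), height = 4,
                               radius = NULL,
                               intrinsics = camera_intrinsics(),
                               distortion = distortion_coefficients(
                                 k1 = -0.12, k2 = 0.02, p1 = 0, p2 = 0, k3 = 0),
                               aim = c(0, 0, 2)) {
  if (is.null(radius)) radius <- pool$diameter / 2 + 0.5
  mk <- function(eye) list(intrinsics = intrinsics, distortion = distortion,
                           pose = look_at_pose(eye, aim), centre = eye)
  list(A = mk(c(radius, 0, -height)), B = mk(c(-radius, 0, -height)))
}

#' Synthetic scene configuration
#'
#' @param pool A [pool_geometry()].
#' @param cameras Two-camera rig as from [default_camera_rig()]; their
#'   horizontal positions must be on opposite sides (angular separation
#'   > 120 degrees).
#' @param fps Frames per second (default 30).
#' @param seed Integer seed; all scene randomness (jitter, pixel noise,
#'   rendering noise) derives from it.
#' @param water A [water_model()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(pool = pool_geometry(), cameras = NULL, fps = 30,
                         seed = 1L, water = water_model()) {
  stopifnot(fps > 0)
  if (is.null(cameras)) cameras <- default_camera_rig(pool)
  a <- cameras[[1]]$centre; b <- cameras[[2]]$centre
  ang <- acos(sum(a[1:2] * b[1:2]) /
                (sqrt(sum(a[1:2]^2)) * sqrt(sum(b[1:2]^2))))
  if (ang <= 2 * pi / 3)
    stop("cameras must view the pool from opposite sides (> 120 deg apart)")
  structure(list(pool = pool, cameras = cameras, fps = fps,
                 seed = as.integer(seed), water = water),
            class = "scene_config")
}

segment_frames <- function(seg, fps) max(1L, round(seg$duration_s * fps))

sample_segment <- function(seg, fps, n, rng_seed) {
  t <- (seq_len(n) - 1L) / fps
  if (seg$type == "circle") {
    turns <- seg$turns
    omega <- 2 * pi * turns / seg$duration_s * if (isTRUE(seg$direction < 0)) -1 else 1
    az0 <- if (is.null(seg$start_azimuth)) 0 else seg$start_azimuth
    th <- az0 + omega * t
    depth <- if (length(seg$depth) == 2)
      seg$depth[1] + (seg$depth[2] - seg$depth[1]) * t / seg$duration_s
    else rep(seg$depth, n)
    cbind(seg$centre[1] + seg$radius * cos(th),
          seg$centre[2] + seg$radius * sin(th),
          depth)
  } else if (seg$type == "dive") {
    zr <- seg$depth_range
    z <- zr[1] + (zr[2] - zr[1]) * (1 - cos(2 * pi * t / seg$period_s)) / 2
    cbind(rep(seg$position[1], n), rep(seg$position[2], n), z)
  } else if (seg$type == "dwell") {
    j <- if (is.null(seg$jitter_m)) 0 else seg$jitter_m
    # Gaussian jitter truncated at +/- jitter_m per axis, so per-frame
    # displacement (and hence speed) is bounded by construction
    noise <- if (j > 0)
      local_rng(rng_seed,
                matrix(pmin(pmax(stats::rnorm(3 * n, 0, j / 2), -j), j), n, 3))
    else matrix(0, n, 3)
    matrix(rep(as.numeric(seg$position), each = n), n, 3) + noise
  } else stop("unknown segment type: ", seg$type)
}

#' Generate a ground-truth trajectory
#'
#' Samples a piecewise motion specification at the scene frame rate and
#' records, from the generating equations themselves, the bookkeeping every
#' downstream stage can be checked against: per-frame zone labels, the ring
#' schedule (frame spans of completed circuits), and the per-frame speed.
#' One extra frame is appended at the end of the last segment so closed
#' circuits include their completing sample.
#'
#' Segment types (each a list with a `type` field):
#' \describe{
#'   \item{circle}{`centre` (x, y), `radius` (m), `turns`, `duration_s`,
#'     optional `direction` (+1 counter-clockwise / -1), `start_azimuth`
#'     (rad), `depth` (scalar, or length-2 for a linear depth ramp).}
#'   \item{dive}{`position` (x, y), `depth_range` (min, max m), `period_s`,
#'     `duration_s`: sinusoidal depth oscillation at a fixed spot.}
#'   \item{dwell}{`position` (x, y, z), `duration_s`, `jitter_m`: stationary
#'     with isotropic Gaussian jitter.}
#' }
#'
#' @param config A [scene_config()].
#' @param segments List of segment specifications.
#' @return An object of class `ground_truth`: list with `positions`
#'   (data.frame `frame`, `time_s`, `x_m`, `y_m`, `z_m`, `valid`), `zones`,
#'   `rings` (data.frame `start_frame`, `end_frame`), `speed_mps`, `fps`.
#' @export
generate_trajectory <- function(config, segments) {
  fps <- config$fps
  pieces <- list(); rings <- list()
  frame0 <- 0L
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    n <- segment_frames(seg, fps)
    if (si == length(segments)) n <- n + 1L   # include the closing sample
    pieces[[si]] <- sample_segment(seg, fps, n, config$seed + si)
    if (seg$type == "circle") {
      fpt <- seg$duration_s * fps / seg$turns  # frames per turn
      for (k in seq_len(floor(seg$turns))) {
        end_local <- ceiling(k * fpt - 1e-9)
        if (end_local <= n - 1L)
          rings[[length(rings) + 1L]] <-
            c(frame0 + ceiling((k - 1) * fpt - 1e-9), frame0 + end_local)
      }
    }
    frame0 <- frame0 + n
  }
  p <- do.call(rbind, pieces)
  nf <- nrow(p)
  r_h <- sqrt(p[, 1]^2 + p[, 2]^2)
  if (any(r_h > config$pool$diameter / 2 + 0.01) ||
      any(p[, 3] < -0.01) || any(p[, 3] > config$pool$max_depth + 0.01))
    stop("trajectory exits the pool bounds")
  positions <- data.frame(frame = seq_len(nf) - 1L,
                          time_s = (seq_len(nf) - 1L) / fps,
                          x_m = p[, 1], y_m = p[, 2], z_m = p[, 3],
                          valid = TRUE)
  speed <- c(NA_real_, sqrt(rowSums(diff(p)^2)) * fps)
  rings_df <- if (length(rings))
    data.frame(start_frame = vapply(rings, `[`, numeric(1), 1),
               end_frame = vapply(rings, `[`, numeric(1), 2))
  else data.frame(start_frame = numeric(0), end_frame = numeric(0))
  structure(list(positions = positions,
                 zones = classify_zone(p[, 1], p[, 2], p[, 3], config$pool),
                 rings = rings_df, speed_mps = speed, fps = fps),
            class = "ground_truth")
}

# Fermat/Snell surface point for projecting an underwater point: finds the
# crossing S on the surface between the camera's and the point's horizontal
# positions such that sin(theta_air) = n * sin(theta_water).
refraction_surface_point <- function(camera_centre, point, water) {
  ch <- camera_centre[1:2]; ph <- point[1:2]
  h1 <- -(camera_centre[3])        # camera height above surface
  h2 <- point[3]                   # point depth
  D <- sqrt(sum((ph - ch)^2))
  if (D < 1e-12) return(c(ch, 0))
  n <- water$refraction_index
  g <- function(s) {
    d1 <- s * D; d2 <- (1 - s) * D
    d1 / sqrt(d1^2 + h1^2) - n * d2 / sqrt(d2^2 + h2^2)
  }
  s <- stats::uniroot(g, c(0, 1), tol = 1e-13)$root
  c(ch + s * (ph - ch), 0)
}

#' Project a ground-truth trajectory through both cameras
#'
#' Each true position is projected to each camera with the full distortion
#' model. Underwater positions are, when `refraction` is on, projected along
#' the Snell-bent path: the air-side ray towards the surface crossing point
#' computed by 1-D root finding on the Snell condition (consistent with
#' [refract_ray()], so reconstruction with the matching water model inverts
#' it). Seeded Gaussian pixel noise is added last; positions behind a camera
#' or projecting outside the sensor are marked invalid.
#'
#' @param gt A `ground_truth` from [generate_trajectory()].
#' @param config A [scene_config()].
#' @param refraction Model refraction at the water surface? (default TRUE)
#' @param pixel_noise_sigma Standard deviation of the added pixel noise.
#' @param seed Seed of the noise stream; default derived from the scene seed.
#' @return List of two centroid data.frames (`camera_id`, `frame`, `u`, `v`,
#'   `valid`), one per camera.
#' @export
project_truth <- function(gt, config, refraction = TRUE,
                          pixel_noise_sigma = 0, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 1000L
  p <- as.matrix(gt$positions[, c("x_m", "y_m", "z_m")])
  n <- nrow(p)
  out <- list()
  for (ci in seq_along(config$cameras)) {
    cam <- config$cameras[[ci]]
    id <- names(config$cameras)[ci]
    ctr <- camera_centre(cam$pose)
    uv <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      tgt <- p[i, ]
      if (refraction && tgt[3] > config$water$surface_z + 1e-12)
        tgt <- refraction_surface_point(ctr, tgt, config$water)
      uv[i, ] <- tryCatch(project_point(tgt, cam$intrinsics, cam$distortion,
                                        cam$pose),
                          error = function(e) c(NA_real_, NA_real_))
    }
    if (pixel_noise_sigma > 0)
      uv <- uv + local_rng(seed + ci,
                           matrix(stats::rnorm(2 * n, 0, pixel_noise_sigma), n, 2))
    valid <- is.finite(uv[, 1]) & is.finite(uv[, 2]) &
      uv[, 1] >= 0 & uv[, 1] <= cam$intrinsics$width - 1 &
      uv[, 2] >= 0 & uv[, 2] <= cam$intrinsics$height - 1
    uv[!valid, ] <- NA_real_
    out[[id]] <- data.frame(camera_id = id, frame = gt$positions$frame,
                            u = uv[, 1], v = uv[, 2], valid = valid)
  }
  out
}

#' Appearance parameters for rendered frames
#'
#' @param blob_semi_axes Ellipse semi-axes in pixels (u, v).
#' @param contrast Grey levels the blob sits above the background.
#' @param background_level Base background grey level (0..255).
#' @param gradient Peak-to-peak grey levels of a smooth horizontal
#'   background gradient.
#' @param noise_sigma Per-frame Gaussian grey noise standard deviation.
#' @return A list.
#' @export
scene_appearance <- function(blob_semi_axes = c(35, 14), contrast = 90,
                             background_level = 110, gradient = 25,
                             noise_sigma = 0) {
  list(blob_semi_axes = blob_semi_axes, contrast = contrast,
       background_level = background_level, gradient = gradient,
       noise_sigma = noise_sigma)
}

render_one_frame <- function(bg, uv, app) {
  img <- bg
  if (all(is.finite(uv)) && app$contrast != 0) {
    a <- app$blob_semi_axes[1]; b <- app$blob_semi_axes[2]
    h <- nrow(bg); w <- ncol(bg)
    u0 <- round(uv[1]); v0 <- round(uv[2])
    uu <- max(0, u0 - ceiling(a)):min(w - 1, u0 + ceiling(a))
    vv <- max(0, v0 - ceiling(b)):min(h - 1, v0 + ceiling(b))
    if (length(uu) && length(vv)) {
      du <- outer(rep(1, length(vv)), uu - uv[1])
      dv <- outer(vv - uv[2], rep(1, length(uu)))
      inside <- (du / a)^2 + (dv / b)^2 <= 1
      sub <- img[vv + 1, uu + 1, drop = FALSE]
      sub[inside] <- sub[inside] + app$contrast
      img[vv + 1, uu + 1] <- sub
    }
  }
  img
}

#' Render simple synthetic frames for both cameras
#'
#' A static background (base level plus a smooth horizontal gradient) with a
#' filled ellipse at each frame's true projected pixel position, plus
#' optional seeded Gaussian grey noise; written as numbered 8-bit PNG frames
#' (`frame_000000.png`, ...), one sub-directory per camera. Fully
#' deterministic under a fixed seed.
#'
#' @param tracks Per-camera pixel tracks from [project_truth()] (noise-free
#'   tracks give frames whose blob centre is the ground truth).
#' @param config A [scene_config()].
#' @param out_dir Output directory; per-camera sub-directories are created.
#' @param appearance A [scene_appearance()].
#' @param seed Noise seed; default derived from the scene seed.
#' @return Named character vector of the per-camera frame directories.
#' @export
render_frames <- function(tracks, config, out_dir,
                          appearance = scene_appearance(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 2000L
  intr <- config$cameras[[1]]$intrinsics
  h <- intr$height; w <- intr$width
  if (2 * appearance$blob_semi_axes[1] >= w || 2 * appearance$blob_semi_axes[2] >= h)
    stop("blob larger than the frame")
  bg <- matrix(appearance$background_level, h, w) +
    matrix(rep(appearance$gradient * sin(seq(0, pi, length.out = w)), each = h), h, w)
  dirs <- character(0)
  for (ci in seq_along(tracks)) {
    tr <- tracks[[ci]]
    d <- file.path(out_dir, paste0("cam_", tr$camera_id[1]))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(tr))) {
      img <- render_one_frame(bg, c(tr$u[i], tr$v[i]), appearance)
      if (appearance$noise_sigma > 0)
        img <- img + local_rng(seed + ci * 100000L + i,
                               matrix(stats::rnorm(h * w, 0, appearance$noise_sigma), h, w))
      img <- pmin(pmax(img, 0), 255)
      png::writePNG(img / 255, file.path(d, sprintf("frame_%06d.png", tr$frame[i])))
    }
    dirs[tr$camera_id[1]] <- d
  }
  dirs
}
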