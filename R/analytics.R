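# Behavioural summaries of a 3D trajectory: zones, speeds, swimming rings,
# region proximity.

#' Pool geometry
#'
#' Describes the arena: a circular pool (default 21 m diameter, 5 m maximum
#' depth), the depth boundary between the shallow shelf and the deep part
#' (default 1.4 m), the horizontal footprint of the maximal-depth floor
#' region ("Deep Area"), and any named regions of interest such as a trainer
#' station or a gate to an adjacent pool.
#'
#' Zone semantics: a position deeper than `shallow_max_depth` is "Bottom";
#' otherwise it is "Deep Area" if its horizontal position lies over the deep
#' footprint and "Shallow Area" if not.
#'
#' @param diameter Pool diameter in metres.
#' @param max_depth Maximum pool depth in metres.
#' @param shallow_max_depth Depth (m) of the shallow shelf; the Bottom zone
#'   starts below this.
#' @param deep_area_polygon Two-column matrix of (x, y) vertices (metres) of
#'   the Deep Area footprint; default: a centred 64-gon of radius
#'   `diameter / 3` (a central deep bowl covering roughly the inner two
#'   thirds of the radius).
#' @param regions Named list of two-column vertex matrices for proximity
#'   analyses.
#' @return An object of class `pool_geometry`.
#' @export
pool_geometry <- function(diameter = 21, max_depth = 5,
                          shallow_max_depth = 1.4,
                          deep_area_polygon = NULL, regions = list()) {
  stopifnot(diameter > 0, max_depth > 0,
            shallow_max_depth > 0, shallow_max_depth < max_depth)
  if (is.null(deep_area_polygon)) {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    deep_area_polygon <- cbind(diameter / 3 * cos(th), diameter / 3 * sin(th))
  }
  deep_area_polygon <- matrix(as.numeric(deep_area_polygon), ncol = 2)
  if (nrow(deep_area_polygon) < 3) stop("deep_area_polygon needs >= 3 vertices")
  structure(list(diameter = diameter, max_depth = max_depth,
                 shallow_max_depth = shallow_max_depth,
                 deep_area_polygon = deep_area_polygon,
                 regions = regions),
            class = "pool_geometry")
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Unwrap a wrapped angle series: map successive differences into (-pi, pi]
# and re-accumulate, so full turns accumulate multiples of 2*pi.
unwrap_angle <- function(theta) {
  d <- diff(theta)
  d <- ((d + pi) %% (2 * pi)) - pi
  theta[1] + cumsum(c(0, d))
}

in_polygon <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

#' Per-frame swimming speed
#'
#' Speed at a frame is the Euclidean displacement from the previous frame
#' divided by the frame interval `1/fps`; frames following a gap (missing or
#' non-consecutive previous frame) carry no speed. The maximum speed is
#' taken over measured (non-interpolated) frames only.
#'
#' @param traj Trajectory data.frame (`frame`, `x_m`, `y_m`, `z_m`, `valid`,
#'   optionally `interpolated`).
#' @param fps Frames per second (default 30).
#' @return Data.frame `frame`, `speed_mps`, `valid`, `interpolated`, with
#'   attribute `max_speed_mps`.
#' @export
compute_speeds <- function(traj, fps = 30) {
  stopifnot(fps > 0)
  n <- nrow(traj)
  interp <- if ("interpolated" %in% names(traj)) traj$interpolated else rep(FALSE, n)
  sp <- rep(NA_real_, n)
  prev_ok <- c(FALSE, traj$valid[-n]) & traj$valid &
    c(FALSE, diff(traj$frame) == 1)
  i <- which(prev_ok)
  if (length(i) == 0) stop("no consecutive pair of valid frames")
  d <- sqrt((traj$x_m[i] - traj$x_m[i - 1])^2 +
            (traj$y_m[i] - traj$y_m[i - 1])^2 +
            (traj$z_m[i] - traj$z_m[i - 1])^2)
  sp[i] <- d * fps
  measured <- sp[i][!(interp[i] | interp[i - 1])]
  out <- data.frame(frame = traj$frame, speed_mps = sp, valid = !is.na(sp),
                    interpolated = interp)
  attr(out, "max_speed_mps") <- if (length(measured)) max(measured) else max(sp[i])
  out
}

#' Frame interval in milliseconds
#'
#' @param fps Frames per second (> 0).
#' @return `1000/fps` rounded to 2 decimals (33.33 ms at 30 fps).
#' @export
frame_interval_ms <- function(fps) {
  if (fps <= 0) stop("fps must be positive")
  round(1000 / fps, 2)
}

#' Speed-category boundaries
#'
#' Partitions `[0, max_speed]` into three equal-width bands -- low,
#' intermediate, high. For a maximum speed of 5.1 m/s the boundaries are
#' 1.7 and 3.4 m/s. An alternative data-driven mode uses the empirical
#' tertiles of the observed speed distribution instead.
#'
#' @param max_speed Maximum observed speed, m/s (> 0).
#' @param speeds Observed speed values; required for `mode = "data"`.
#' @param mode `"equal_width"` (default) or `"data"` (empirical tertiles).
#' @return Numeric `c(low_upper, mid_upper)`.
#' @export
speed_category_bounds <- function(max_speed, speeds = NULL,
                                  mode = c("equal_width", "data")) {
  mode <- match.arg(mode)
  if (max_speed <= 0) stop("max_speed must be positive")
  if (mode == "equal_width") c(max_speed / 3, 2 * max_speed / 3)
  else {
    if (is.null(speeds)) stop("mode = 'data' needs the speed series")
    as.numeric(stats::quantile(speeds, c(1 / 3, 2 / 3), na.rm = TRUE,
                               names = FALSE, type = 7))
  }
}

#' Time spent in each speed category
#'
#' Counts valid speed frames per band -- low `[0, b1)`, intermediate
#' `[b1, b2)`, high `[b2, max]` -- and converts to minutes and to the
#' percentage of valid speed frames.
#'
#' @param speeds Output of [compute_speeds()].
#' @param fps Frames per second.
#' @param bounds Band boundaries; default from [speed_category_bounds()] at
#'   the series' maximum speed.
#' @return Data.frame `category`, `frames`, `minutes`, `percent`, with
#'   attributes `bounds` and `max_speed_mps`.
#' @export
speed_time_summary <- function(speeds, fps = 30, bounds = NULL) {
  v <- speeds$speed_mps[speeds$valid]
  maxs <- attr(speeds, "max_speed_mps")
  if (is.null(maxs)) maxs <- max(v)
  if (is.null(bounds)) bounds <- speed_category_bounds(maxs)
  cat_of <- ifelse(v < bounds[1], "low",
                   ifelse(v < bounds[2], "intermediate", "high"))
  lev <- c("low", "intermediate", "high")
  counts <- as.integer(table(factor(cat_of, levels = lev)))
  out <- data.frame(category = lev, frames = counts,
                    minutes = counts / fps / 60,
                    percent = if (length(v)) 100 * counts / length(v) else 0)
  attr(out, "bounds") <- bounds
  attr(out, "max_speed_mps") <- maxs
  out
}

#' Classify positions into pool zones
#'
#' "Bottom" for any position deeper than the shallow-shelf depth; otherwise
#' "Deep Area" when the horizontal position lies over the deep footprint,
#' else "Shallow Area". Every valid position gets exactly one label. Depth
#' is evaluated first: Bottom is defined by depth alone.
#'
#' @param x,y,z Position coordinates (metres, z = depth positive downward);
#'   vectorized.
#' @param pool A [pool_geometry()].
#' @return Character vector of zone labels (`NA` for non-finite positions).
#' @export
classify_zone <- function(x, y, z, pool = pool_geometry()) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(NA_character_, length(x))
  if (!any(ok)) return(out)
  deep <- in_polygon(x[ok], y[ok], pool$deep_area_polygon)
  out[ok] <- ifelse(z[ok] > pool$shallow_max_depth, "Bottom",
                    ifelse(deep, "Deep Area", "Shallow Area"))
  out
}

#' Zone occupancy summary
#'
#' Frame counts per zone converted to minutes (`count / fps / 60`) and to the
#' percentage of valid frames.
#'
#' @param traj Trajectory data.frame.
#' @param pool A [pool_geometry()].
#' @param fps Frames per second.
#' @return Data.frame `zone`, `frames`, `minutes`, `percent`.
#' @export
occupancy_summary <- function(traj, pool = pool_geometry(), fps = 30) {
  v <- traj$valid
  zones <- classify_zone(traj$x_m[v], traj$y_m[v], traj$z_m[v], pool)
  lev <- c("Deep Area", "Shallow Area", "Bottom")
  counts <- as.integer(table(factor(zones, levels = lev)))
  data.frame(zone = lev, frames = counts, minutes = counts / fps / 60,
             percent = if (sum(v)) 100 * counts / sum(v) else 0)
}

#' Detect complete swimming rings
#'
#' A swimming ring is one complete circuit of the pool: a maximal span of
#' frames over which the cumulative unwrapped azimuth of the horizontal
#' position about the ring centre changes by 2*pi in either direction.
#' Spans whose mean horizontal radius is below `min_radius` (tight pivoting
#' rather than pool circuits) are rejected. Rings are non-overlapping and
#' consecutive: the frame at which the accumulated angle first reaches
#' +/- 2*pi ends the ring and starts the next.
#'
#' @param traj Trajectory data.frame.
#' @param pool A [pool_geometry()]; the default ring centre is the centroid
#'   of its Deep Area footprint.
#' @param fps Frames per second.
#' A circuit that ends within `end_tolerance` radians of closure at the last
#' frame of the data is counted as complete: with measurement noise, a
#' session holding exactly k circuits would otherwise lose its last one to a
#' fraction of a degree.
#'
#' @param min_radius Minimum mean horizontal radius (m) for a valid ring.
#' @param centre Optional ring centre `c(x, y)` overriding the default.
#' @param end_tolerance Angular closure tolerance (rad) applied only at the
#'   end of the trajectory; default 0.1 (about 1.6% of a turn).
#' @return Data.frame with one row per ring and the [ring_metrics()] columns;
#'   zero rows when no ring completes.
#' @export
detect_rings <- function(traj, pool = pool_geometry(), fps = 30,
                         min_radius = 2, centre = NULL, end_tolerance = 0.1) {
  if (is.null(centre)) centre <- polygon_centroid(pool$deep_area_polygon)
  v <- which(traj$valid)
  empty <- data.frame(ring = integer(0), start_frame = integer(0),
                      end_frame = integer(0), duration_frames = integer(0),
                      duration_s = numeric(0), path_length_m = numeric(0),
                      start_end_distance_m = numeric(0),
                      mean_speed_mps = numeric(0), mean_radius_m = numeric(0))
  if (length(v) < 3) return(empty)
  theta <- atan2(traj$y_m[v] - centre[2], traj$x_m[v] - centre[1])
  theta <- unwrap_angle(theta)
  rings <- list()
  add_ring <- function(start, i) {
    span <- start:i
    r <- sqrt((traj$x_m[v[span]] - centre[1])^2 +
              (traj$y_m[v[span]] - centre[2])^2)
    if (mean(r) >= min_radius)
      rings[[length(rings) + 1L]] <<- c(traj$frame[v[start]], traj$frame[v[i]])
  }
  # boundaries are crossings of j * 2*pi relative to the fixed start azimuth,
  # not of 2*pi from the previous (noisy) boundary sample: resetting at each
  # crossing would let the per-ring overshoot accumulate and starve the
  # final circuit of its closing fraction
  delta <- abs(theta - theta[1])
  start <- 1L
  j <- 1L
  n <- length(v)
  for (i in seq(2L, n)) {
    if (delta[i] >= j * 2 * pi - 1e-9) {
      add_ring(start, i)
      start <- i
      j <- j + 1L
    }
  }
  if (start < n && delta[n] >= j * 2 * pi - end_tolerance)
    add_ring(start, n)
  if (length(rings) == 0L) return(empty)
  out <- do.call(rbind, lapply(seq_along(rings), function(k) {
    m <- ring_metrics(traj, rings[[k]][1], rings[[k]][2], fps, centre)
    cbind(ring = k, m)
  }))
  rownames(out) <- NULL
  out
}

#' Metrics of one swimming ring
#'
#' Duration in frames and seconds, the straight-line distance between the
#' ring's first and last positions, the along-path length (sum of
#' inter-frame displacements), the mean speed (path length over duration),
#' and the mean horizontal radius about the ring centre. Both the start-end
#' distance and the path length are reported as ring "size": for a closed
#' circuit the former is near zero by construction, so the path length is
#' the informative one.
#'
#' @param traj Trajectory data.frame.
#' @param start_frame,end_frame Ring span (frame numbers, inclusive).
#' @param fps Frames per second.
#' @param centre Ring centre `c(x, y)`.
#' @return One-row data.frame.
#' @export
ring_metrics <- function(traj, start_frame, end_frame, fps = 30,
                         centre = c(0, 0)) {
  stopifnot(end_frame > start_frame)
  sel <- which(traj$frame >= start_frame & traj$frame <= end_frame & traj$valid)
  p <- cbind(traj$x_m[sel], traj$y_m[sel], traj$z_m[sel])
  dur_f <- end_frame - start_frame
  dur_s <- dur_f / fps
  path <- if (nrow(p) > 1) sum(sqrt(rowSums(diff(p)^2))) else 0
  se <- if (nrow(p) > 1) sqrt(sum((p[nrow(p), ] - p[1, ])^2)) else 0
  data.frame(start_frame = start_frame, end_frame = end_frame,
             duration_frames = dur_f, duration_s = dur_s,
             path_length_m = path, start_end_distance_m = se,
             mean_speed_mps = path / dur_s,
             mean_radius_m = mean(sqrt((p[, 1] - centre[1])^2 +
                                       (p[, 2] - centre[2])^2)))
}

#' Time spent over a named region
#'
#' Counts valid frames whose horizontal position falls inside the region
#' polygon (e.g. near the trainer station or a gate to an adjacent pool).
#'
#' @param traj Trajectory data.frame.
#' @param polygon Two-column (x, y) vertex matrix, metres.
#' @param fps Frames per second.
#' @return List with `frames`, `minutes`, `percent` (of valid frames).
#' @export
region_time <- function(traj, polygon, fps = 30) {
  polygon <- matrix(as.numeric(polygon), ncol = 2)
  if (nrow(polygon) < 3) stop("degenerate region polygon")
  v <- traj$valid
  inside <- sum(in_polygon(traj$x_m[v], traj$y_m[v], polygon))
  list(frames = inside, minutes = inside / fps / 60,
       percent = if (sum(v)) 100 * inside / sum(v) else 0)
}

#' Full behavioural report for a trajectory
#'
#' Zone occupancy, speed categories, swimming rings, and per-region
#' proximity times, bundled for serialization.
#'
#' @param traj Trajectory data.frame.
#' @param pool A [pool_geometry()].
#' @param fps Frames per second.
#' @return A list: `occupancy`, `speed` (summary + bounds + max), `rings`,
#'   `regions`.
#' @export
analyze_trajectory <- function(traj, pool = pool_geometry(), fps = 30) {
  speeds <- compute_speeds(traj, fps)
  sp_sum <- speed_time_summary(speeds, fps)
  rings <- detect_rings(traj, pool, fps)
  regions <- lapply(pool$regions, function(p) region_time(traj, p, fps))
  list(occupancy = occupancy_summary(traj, pool, fps),
       speed = list(max_speed_mps = attr(sp_sum, "max_speed_mps"),
                    bounds_mps = attr(sp_sum, "bounds"),
                    summary = sp_sum),
       rings = rings,
       regions = regions)
}
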