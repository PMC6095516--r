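# Pinhole camera with radial-tangential distortion, pose estimation.

#' Camera intrinsic parameters
#'
#' Focal lengths and principal point in pixel units, plus the sensor size.
#' Defaults are the calibrated values for the 1280x720 wide-angle cameras the
#' method was developed with: a single focal value 654.55 px for both axes and
#' the principal point at the sensor centre under 0-based pixel indexing
#' (cx = 1279/2, cy = 719/2).
#'
#' @param fx,fy Focal lengths in pixel units (> 0).
#' @param cx,cy Principal point (column, row) in 0-based pixels.
#' @param width,height Sensor size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx = 654.55, fy = 654.55,
                              cx = 1279 / 2, cy = 719 / 2,
                              width = 1280L, height = 720L) {
  stopifnot(is.finite(fx), is.finite(fy), fx > 0, fy > 0,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Lens distortion coefficients
#'
#' Radial (`k1`, `k2`, `k3`) and tangential (`p1`, `p2`) coefficients of the
#' standard radial-tangential lens model, stored in the conventional
#' `(k1, k2, p1, p2, k3)` order. Defaults are the calibrated values for the
#' wide-angle cameras; the strong negative `k1` captures the fish-eye
#' compression of the lens.
#'
#' @param k1,k2,k3 Radial coefficients (dimensionless).
#' @param p1,p2 Tangential coefficients (dimensionless).
#' @return An object of class `distortion_coefficients`.
#' @export
distortion_coefficients <- function(k1 = -0.335050702095, k2 = 0.120226070285,
                                    p1 = 0, p2 = 0, k3 = -0.0201695654541) {
  v <- c(k1 = k1, k2 = k2, p1 = p1, p2 = p2, k3 = k3)
  stopifnot(all(is.finite(v)))
  structure(as.list(v), class = "distortion_coefficients")
}

#' Rigid camera pose (world to camera)
#'
#' @param rotation 3x3 orthonormal rotation matrix mapping world coordinates
#'   into the camera frame.
#' @param translation Length-3 translation (metres) so that
#'   `x_cam = rotation %*% x_world + translation`.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation, translation) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "camera_pose")
}

#' Camera centre in world coordinates
#' @param pose A [camera_pose()].
#' @return Length-3 numeric vector (metres).
#' @export
camera_centre <- function(pose) {
  drop(-t(pose$rotation) %*% pose$translation)
}

#' A viewing ray in world coordinates
#'
#' @param origin Length-3 origin (metres), typically the camera focal point.
#' @param direction Length-3 direction; normalized to unit length.
#' @return An object of class `ray`.
#' @export
ray <- function(origin, direction) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("ray direction must be non-zero")
  structure(list(origin = origin, direction = direction / n), class = "ray")
}

as_xy_matrix <- function(xy) {
  if (is.matrix(xy)) xy else matrix(as.numeric(xy), ncol = 2)
}

#' Apply lens distortion to normalized camera coordinates
#'
#' Maps ideal normalized coordinates `(x', y') = (x/z, y/z)` to distorted
#' coordinates with the radial-tangential model
#' `x_d = x'(1 + k1 r^2 + k2 r^4 + k3 r^6) + 2 p1 x'y' + p2 (r^2 + 2 x'^2)`
#' (and symmetrically for `y_d`), where `r^2 = x'^2 + y'^2`.
#'
#' @param xy Length-2 vector or Nx2 matrix of normalized coordinates.
#' @param coeffs A [distortion_coefficients()].
#' @return Same shape as `xy`.
#' @export
distort_point <- function(xy, coeffs) {
  m <- as_xy_matrix(xy)
  if (!all(is.finite(m))) stop("non-finite normalized coordinates")
  x <- m[, 1]; y <- m[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + coeffs$k1 * r2 + coeffs$k2 * r2^2 + coeffs$k3 * r2^3
  xd <- x * radial + 2 * coeffs$p1 * x * y + coeffs$p2 * (r2 + 2 * x^2)
  yd <- y * radial + coeffs$p1 * (r2 + 2 * y^2) + 2 * coeffs$p2 * x * y
  out <- cbind(xd, yd, deparse.level = 0)
  if (is.matrix(xy)) out else drop(out)
}

#' Invert the lens distortion model
#'
#' Fixed-point iteration: starting from the distorted coordinates, repeatedly
#' divides out the radial factor and subtracts the tangential terms until the
#' forward model reproduces the input within `tol`.
#'
#' @param xy Length-2 vector or Nx2 matrix of distorted normalized coordinates.
#' @param coeffs A [distortion_coefficients()].
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the forward residual (default 1e-10).
#' @return Undistorted coordinates, same shape as `xy`.
#' @export
undistort_point <- function(xy, coeffs, max_iter = 100L, tol = 1e-10) {
  m <- as_xy_matrix(xy)
  if (!all(is.finite(m))) stop("non-finite distorted coordinates")
  xd <- m[, 1]; yd <- m[, 2]
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + coeffs$k1 * r2 + coeffs$k2 * r2^2 + coeffs$k3 * r2^3
    if (any(radial <= 0)) stop("point outside the invertible region of the distortion model")
    x_new <- (xd - (2 * coeffs$p1 * x * y + coeffs$p2 * (r2 + 2 * x^2))) / radial
    y_new <- (yd - (coeffs$p1 * (r2 + 2 * y^2) + 2 * coeffs$p2 * x * y)) / radial
    delta <- max(abs(x_new - x), abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < tol) break
  }
  fwd <- distort_point(cbind(x, y), coeffs)
  err <- pmax(abs(fwd[, 1] - xd), abs(fwd[, 2] - yd))
  if (any(err > 1e-8)) {
    bad <- which.max(err)
    stop(sprintf("undistortion failed to converge at point (%g, %g)",
                 xd[bad], yd[bad]))
  }
  out <- cbind(x, y, deparse.level = 0)
  if (is.matrix(xy)) out else drop(out)
}

#' Project world points to pixel coordinates
#'
#' World -> camera rigid transform, perspective divide, lens distortion, then
#' intrinsic mapping `u = fx x_d + cx`, `v = fy y_d + cy`. The returned pixels
#' may fall outside the sensor; callers filter by bounds.
#'
#' @param world Length-3 vector or Nx3 matrix of world points (metres).
#' @param intr A [camera_intrinsics()].
#' @param coeffs A [distortion_coefficients()].
#' @param pose A [camera_pose()].
#' @return `(u, v)` pixels, same shape convention as the input.
#' @export
project_point <- function(world, intr, coeffs, pose) {
  w <- if (is.matrix(world)) world else matrix(as.numeric(world), ncol = 3)
  cam <- t(pose$rotation %*% t(w) + pose$translation)
  if (any(cam[, 3] <= 0))
    stop("point at or behind the camera plane cannot be projected")
  norm_xy <- cbind(cam[, 1] / cam[, 3], cam[, 2] / cam[, 3])
  d <- distort_point(norm_xy, coeffs)
  d <- matrix(d, ncol = 2)
  out <- cbind(intr$fx * d[, 1] + intr$cx, intr$fy * d[, 2] + intr$cy,
               deparse.level = 0)
  if (is.matrix(world)) out else drop(out)
}

#' Back-project a pixel to a world-space viewing ray
#'
#' Undistorts the pixel, forms the camera-frame points at depths z = 0 and
#' z = 1 via `x = (u - cx) z / fx`, `y = (v - cy) z / fy`, maps both through
#' the inverse pose, and returns the ray through them. The ray origin is the
#' camera centre in world coordinates.
#'
#' @param uv Length-2 pixel coordinates `(u, v)`, 0-based, origin top-left.
#' @inheritParams project_point
#' @return A [ray()].
#' @export
pixel_to_ray <- function(uv, intr, coeffs, pose) {
  uv <- as.numeric(uv)
  if (uv[1] < 0 || uv[1] > intr$width - 1 || uv[2] < 0 || uv[2] > intr$height - 1)
    stop(sprintf("pixel (%g, %g) outside image bounds", uv[1], uv[2]))
  nd <- undistort_point(c((uv[1] - intr$cx) / intr$fx,
                          (uv[2] - intr$cy) / intr$fy), coeffs)
  Rt <- t(pose$rotation)
  origin <- drop(-Rt %*% pose$translation)           # camera-frame z = 0
  p1 <- drop(Rt %*% (c(nd[1], nd[2], 1) - pose$translation))  # z = 1
  ray(origin, p1 - origin)
}

# --- rotation parameterisations ------------------------------------------

rodrigues_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  k <- rvec / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    i <- which.max(k)
    k <- A[, i] / k[i]
    return(theta * k / sqrt(sum(k^2)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  theta * ax
}

euler_zyx <- function(yaw, pitch, roll) {
  Rz <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(pitch), 0, -sin(pitch), 0, 1, 0, sin(pitch), 0, cos(pitch)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(roll), sin(roll), 0, -sin(roll), cos(roll)), 3, 3)
  Rz %*% Ry %*% Rx
}

# --- PnP -----------------------------------------------------------------

# DLT estimate of [R | t] from >= 6 world points and undistorted normalized
# image coordinates; rotation re-orthonormalised by SVD.
pnp_dlt <- function(world, norm_xy) {
  n <- nrow(world)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(world[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 4), -norm_xy[i, 1] * X)
    A[2 * i, ]     <- c(rep(0, 4), X, -norm_xy[i, 2] * X)
  }
  p <- svd(A)$v[, 12]
  P <- matrix(p, 3, 4, byrow = TRUE)
  M <- P[, 1:3]
  # fix overall sign so points are in front of the camera
  depths <- world %*% t(M)[, 3, drop = FALSE] + P[3, 4]
  if (mean(depths > 0) < 0.5) { P <- -P; M <- -M }
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  scale <- mean(s$d)
  list(rotation = R, translation = P[, 4] / scale)
}

# Given a rotation, translation is linear in the projection equations.
solve_translation <- function(R, world, norm_xy) {
  n <- nrow(world)
  A <- matrix(0, 2 * n, 3); b <- numeric(2 * n)
  RX <- world %*% t(R)
  for (i in seq_len(n)) {
    A[2 * i - 1, ] <- c(-1, 0, norm_xy[i, 1])
    b[2 * i - 1] <- RX[i, 1] - norm_xy[i, 1] * RX[i, 3]
    A[2 * i, ] <- c(0, -1, norm_xy[i, 2])
    b[2 * i] <- RX[i, 2] - norm_xy[i, 2] * RX[i, 3]
  }
  qr.solve(A, b)
}

reprojection_residuals <- function(par, world, pix, intr, coeffs) {
  R <- rodrigues_to_matrix(par[1:3])
  tr <- par[4:6]
  cam <- t(R %*% t(world) + tr)
  z <- pmax(cam[, 3], 1e-9)
  d <- distort_point(cbind(cam[, 1] / z, cam[, 2] / z), coeffs)
  d <- matrix(d, ncol = 2)
  uv <- cbind(intr$fx * d[, 1] + intr$cx, intr$fy * d[, 2] + intr$cy)
  penalty <- ifelse(cam[, 3] <= 0, 1e4, 0)
  as.numeric(uv - pix) + rep(penalty, 2)
}

refine_pose <- function(R0, t0, world, pix, intr, coeffs) {
  par0 <- c(matrix_to_rodrigues(R0), t0)
  fit <- minpack.lm::nls.lm(par = par0, fn = reprojection_residuals,
                            world = world, pix = pix, intr = intr,
                            coeffs = coeffs,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  list(rotation = rodrigues_to_matrix(fit$par[1:3]),
       translation = fit$par[4:6],
       rss = sum(fit$fvec^2))
}

pose_reproj_errors <- function(R, tr, world, pix, intr, coeffs) {
  cam <- t(R %*% t(world) + tr)
  bad <- cam[, 3] <= 0
  z <- ifelse(bad, 1, cam[, 3])
  d <- distort_point(cbind(cam[, 1] / z, cam[, 2] / z), coeffs)
  d <- matrix(d, ncol = 2)
  uv <- cbind(intr$fx * d[, 1] + intr$cx, intr$fy * d[, 2] + intr$cy)
  e <- sqrt(rowSums((uv - pix)^2))
  e[bad] <- Inf
  e
}

# Coarse orientation grid + linear translation solve; used to initialize the
# nonlinear refinement when a DLT (>= 6 points) is not available.
pose_grid_init <- function(world, norm_xy, intr, coeffs, pix) {
  best <- NULL; best_err <- Inf
  yaws <- seq(0, 2 * pi - 1e-9, by = pi / 6)
  pitches <- seq(-pi / 2, pi / 2, by = pi / 6)
  rolls <- seq(0, 2 * pi - 1e-9, by = pi / 6)
  for (yaw in yaws) for (pitch in pitches) for (roll in rolls) {
    R <- euler_zyx(yaw, pitch, roll)
    tr <- tryCatch(solve_translation(R, world, norm_xy), error = function(e) NULL)
    if (is.null(tr)) next
    e <- pose_reproj_errors(R, tr, world, pix, intr, coeffs)
    m <- mean(pmin(e, 1e6))
    if (is.finite(m) && m < best_err) { best_err <- m; best <- list(R = R, tr = tr) }
  }
  best
}

#' Estimate camera pose from landmark correspondences (RANSAC PnP)
#'
#' Robust Perspective-n-Point: repeatedly fits a pose to a minimal sample of
#' correspondences, scores it by the number of points whose reprojection error
#' is at most `inlier_threshold_px`, and finally refits a full nonlinear
#' least-squares pose on the best consensus set.
#'
#' @param world Nx3 matrix of landmark world coordinates (metres).
#' @param pixels Nx2 matrix of observed pixel positions, same row order.
#' @param intr A [camera_intrinsics()].
#' @param coeffs A [distortion_coefficients()].
#' @param n_iter RANSAC iterations (default 200).
#' @param inlier_threshold_px Reprojection-error threshold for inliers
#'   (default 5 px).
#' @param seed Integer seed for the RANSAC sampler; the global RNG state is
#'   left untouched.
#' @return A list with elements `pose` ([camera_pose()]), `inliers` (integer
#'   indices), and `residuals_px` (per-point reprojection errors).
#' @export
estimate_pose_ransac <- function(world, pixels, intr, coeffs,
                                 n_iter = 200L, inlier_threshold_px = 5,
                                 seed = 1L) {
  world <- matrix(as.numeric(world), ncol = 3)
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  n <- nrow(world)
  if (n < 5) stop("at least 5 calibration points are required")
  if (nrow(pixels) != n) stop("world/pixel point counts differ")
  # undistort per point; points outside the invertible region of the lens
  # model cannot be genuine landmark detections and are treated as outliers
  norm_xy <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    norm_xy[i, ] <- tryCatch(
      undistort_point(c((pixels[i, 1] - intr$cx) / intr$fx,
                        (pixels[i, 2] - intr$cy) / intr$fy), coeffs),
      error = function(e) c(NA_real_, NA_real_))
  }
  usable <- which(is.finite(norm_xy[, 1]))
  if (length(usable) < 5)
    stop("fewer than 5 calibration points are within the invertible lens field")

  fit_sample <- function(idx) {
    init <- tryCatch(pnp_dlt(world[idx, , drop = FALSE],
                             norm_xy[idx, , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(init)) return(NULL)
    tryCatch(refine_pose(init$rotation, init$translation,
                         world[idx, , drop = FALSE],
                         pixels[idx, , drop = FALSE], intr, coeffs),
             error = function(e) NULL)
  }

  best <- NULL; best_inliers <- integer(0)
  if (length(usable) >= 6) {
    samples <- local_rng(seed, {
      lapply(seq_len(n_iter), function(i) usable[sample.int(length(usable), 6)])
    })
    for (idx in samples) {
      fit <- fit_sample(idx)
      if (is.null(fit)) next
      e <- pose_reproj_errors(fit$rotation, fit$translation, world, pixels,
                              intr, coeffs)
      inl <- which(e <= inlier_threshold_px)
      if (length(inl) > length(best_inliers)) {
        best <- fit; best_inliers <- inl
        if (length(inl) == n) break
      }
    }
  }
  if (is.null(best)) {
    # 5 usable points, or no DLT sample succeeded: coarse orientation search
    init <- pose_grid_init(world[usable, , drop = FALSE],
                           norm_xy[usable, , drop = FALSE], intr, coeffs,
                           pixels[usable, , drop = FALSE])
    if (is.null(init)) stop("pose estimation failed: no initialization found")
    best <- refine_pose(init$R, init$tr, world[usable, , drop = FALSE],
                        pixels[usable, , drop = FALSE], intr, coeffs)
    e <- pose_reproj_errors(best$rotation, best$translation, world, pixels,
                            intr, coeffs)
    best_inliers <- which(e <= inlier_threshold_px)
  }
  if (length(best_inliers) < 5)
    stop("no consensus set of at least 5 inliers found")
  final <- refine_pose(best$rotation, best$translation,
                       world[best_inliers, , drop = FALSE],
                       pixels[best_inliers, , drop = FALSE], intr, coeffs)
  resid <- pose_reproj_errors(final$rotation, final$translation, world, pixels,
                              intr, coeffs)
  inliers <- which(resid <= inlier_threshold_px)
  list(pose = camera_pose(final$rotation, final$translation),
       inliers = sort(inliers),
       residuals_px = resid)
}

# Evaluate `expr` under a private RNG stream; restores the caller's state.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a pose looking from one point toward another
#'
#' Convenience constructor for synthetic rigs: places the camera at `eye`
#' with its optical axis through `target`. The world frame has z pointing
#' down (depth), so the default "up" reference is the world -z axis.
#'
#' @param eye Camera position, world metres.
#' @param target Point the optical axis passes through.
#' @param up Approximate up direction in world coordinates.
#' @return A [camera_pose()].
#' @export
look_at_pose <- function(eye, target, up = c(0, 0, -1)) {
  eye <- as.numeric(eye); target <- as.numeric(target)
  fwd <- target - eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- pracma::cross(fwd, up)
  if (sqrt(sum(right^2)) < 1e-12) stop("up vector parallel to view direction")
  right <- right / sqrt(sum(right^2))
  down <- pracma::cross(fwd, right)   # camera y axis; rows form det = +1
  R <- rbind(right, down, fwd, deparse.level = 0)
  dimnames(R) <- NULL
  camera_pose(R, drop(-R %*% eye))
}
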