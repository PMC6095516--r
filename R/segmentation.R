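# Background-subtraction blob detection.
#
# Frames are numeric matrices [height x width] in grey levels 0..255
# (multi-channel frames are [height x width x channels]); pixel (u, v) is
# 0-based with u = column, v = row, so it lives at matrix[v + 1, u + 1].

#' Segmentation parameters
#'
#' Tuning knobs of the per-frame detection chain. These correspond to the
#' manually tuned imaging filters of the original field workflow (adaptive
#' threshold, colour-range gate, erosion and dilation): lighting and water
#' glare vary between sessions, so the values are configuration, not learned.
#'
#' @param adaptive_block Odd side length (pixels) of the local-mean window of
#'   the adaptive threshold.
#' @param adaptive_offset Grey levels added to the local mean; a pixel of the
#'   difference image is foreground only if it exceeds local mean + offset.
#' @param colour_range Optional list with `min` and `max` vectors (one value
#'   per channel of the original frame); when set, foreground pixels must also
#'   have all original channels inside the range.
#' @param erosion_radius,dilation_radius Disc radii (pixels) of the
#'   morphological cleanup; 0 disables the step.
#' @param min_blob_area,max_blob_area Component-area bounds in pixels;
#'   components outside the bounds are discarded. The defaults
#'   `[200, 50000]` are engineering defaults for a 1280x720 sensor.
#' @param mask Optional binary matrix (same size as the frames) marking the
#'   tracking area; everything outside is ignored.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(adaptive_block = 101L, adaptive_offset = 10,
                                colour_range = NULL,
                                erosion_radius = 2L, dilation_radius = 2L,
                                min_blob_area = 200L, max_blob_area = 50000L,
                                mask = NULL) {
  stopifnot(adaptive_block >= 1, erosion_radius >= 0, dilation_radius >= 0,
            min_blob_area < max_blob_area, adaptive_offset >= 0)
  if (adaptive_block %% 2 == 0) stop("adaptive_block must be odd")
  structure(list(adaptive_block = as.integer(adaptive_block),
                 adaptive_offset = adaptive_offset,
                 colour_range = colour_range,
                 erosion_radius = as.integer(erosion_radius),
                 dilation_radius = as.integer(dilation_radius),
                 min_blob_area = as.integer(min_blob_area),
                 max_blob_area = as.integer(max_blob_area),
                 mask = mask),
            class = "segmentation_params")
}

frame_grey <- function(frame) {
  if (length(dim(frame)) == 3) {
    # luminance as plain channel mean; channel weighting is a colour_range job
    apply(frame, c(1, 2), mean)
  } else frame
}

#' Static background model from reference frames
#'
#' Per-pixel median over a set of frames. A static background with manual
#' re-tuning reflects the original workflow, where the model depended on the
#' natural light of each session.
#'
#' @param frames List of frame matrices (grey, same size).
#' @return Matrix of the same size.
#' @export
background_model <- function(frames) {
  stopifnot(length(frames) >= 1)
  g <- lapply(frames, frame_grey)
  d <- dim(g[[1]])
  arr <- array(unlist(g), dim = c(d, length(g)))
  apply(arr, c(1, 2), stats::median)
}

#' Absolute frame-background difference
#'
#' Per-pixel absolute difference between a frame and the background model,
#' zeroed outside the tracking-area mask.
#'
#' @param frame Frame matrix (grey or multi-channel).
#' @param background Background matrix (grey), same height/width.
#' @param params A [segmentation_params()] (for the mask).
#' @return Difference matrix, grey levels.
#' @export
subtract_background <- function(frame, background, params = segmentation_params()) {
  g <- frame_grey(frame)
  if (!all(dim(g) == dim(background)))
    stop("frame and background sizes differ")
  d <- abs(g - background)
  if (!is.null(params$mask)) {
    if (!all(dim(params$mask) == dim(g))) stop("mask size differs from frame")
    d <- d * (params$mask != 0)
  }
  d
}

# Exact local mean over a (2r+1)^2 window clipped at the borders, via an
# integral image: O(1) per pixel regardless of window size.
local_mean <- function(x, block) {
  cpp_local_mean(x, (block - 1L) %/% 2L)
}

#' Adaptive threshold with optional colour gate
#'
#' A pixel is foreground iff its difference value strictly exceeds the local
#' mean (over `adaptive_block`) plus `adaptive_offset`, and, when a
#' `colour_range` is configured, the original frame's channels at that pixel
#' all lie inside the range. Masked-out pixels are always background.
#'
#' @param diff Difference image from [subtract_background()].
#' @param params A [segmentation_params()].
#' @param frame Original frame; required only when `colour_range` is set.
#' @return Logical matrix (TRUE = foreground).
#' @export
binarize <- function(diff, params = segmentation_params(), frame = NULL) {
  if (params$adaptive_block %% 2 == 0) stop("adaptive_block must be odd")
  fg <- diff > local_mean(diff, params$adaptive_block) + params$adaptive_offset
  if (!is.null(params$colour_range)) {
    if (is.null(frame)) stop("colour_range set but no frame supplied")
    ch <- if (length(dim(frame)) == 3) dim(frame)[3] else 1L
    rng <- params$colour_range
    ok <- matrix(TRUE, nrow(diff), ncol(diff))
    for (k in seq_len(ch)) {
      band <- if (ch == 1L) frame else frame[, , k]
      ok <- ok & band >= rng$min[k] & band <= rng$max[k]
    }
    fg <- fg & ok
  }
  if (!is.null(params$mask)) fg <- fg & (params$mask != 0)
  fg
}

#' Morphological cleanup: erosion then dilation
#'
#' Disc-shaped structuring elements; radius 0 is the identity. Removes
#' speckle noise smaller than the erosion disc while restoring the extent of
#' surviving blobs.
#'
#' @param bin Logical or 0/1 matrix.
#' @param params A [segmentation_params()].
#' @return Logical matrix.
#' @export
morphological_cleanup <- function(bin, params = segmentation_params()) {
  x <- bin != 0
  if (params$erosion_radius > 0 && any(x)) x <- binary_erode(x, params$erosion_radius)
  if (params$dilation_radius > 0 && any(x)) {
    r <- params$dilation_radius
    # dilation only grows around surviving foreground: run it on a padded crop
    idx <- which(x, arr.ind = TRUE)
    r1 <- max(1L, min(idx[, 1]) - r); r2 <- min(nrow(x), max(idx[, 1]) + r)
    c1 <- max(1L, min(idx[, 2]) - r); c2 <- min(ncol(x), max(idx[, 2]) + r)
    x[r1:r2, c1:c2] <- binary_dilate(x[r1:r2, c1:c2, drop = FALSE], r)
  }
  x
}

# Disc-shaped binary erosion/dilation (offsets with dv^2 + du^2 <= r^2);
# pixels beyond the image border count as background.
binary_erode <- function(x, r) {
  out <- cpp_binary_erode(x, as.integer(r))
  dim(out) <- dim(x)
  out
}

binary_dilate <- function(x, r) {
  out <- cpp_binary_dilate(x, as.integer(r))
  dim(out) <- dim(x)
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connective, so labels
# touching diagonally are merged afterwards with a union-find over label ids.
label_components_8 <- function(bin) {
  lab <- EBImage::bwlabel((bin != 0) * 1)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Extract the animal blob centroid from a binary image
#'
#' Labels 8-connected components, discards components with area outside
#' `[min_blob_area, max_blob_area]`, and returns the largest survivor's
#' area-weighted centroid. Absence of a detection is a value (`NULL`), not an
#' error. Area ties are broken by the lowest (v, u) of the component's
#' top-left bounding corner.
#'
#' @param bin Logical or 0/1 matrix.
#' @param params A [segmentation_params()].
#' @return A list `blob(centroid = c(u, v), area, bbox = c(u_min, v_min,
#'   u_max, v_max))`, or `NULL` when no component survives the area bounds.
#' @export
extract_centroid <- function(bin, params = segmentation_params()) {
  # label within the foreground bounding box only; outside is background
  fg <- which(bin != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(NULL)
  r1 <- min(fg[, 1]); r2 <- max(fg[, 1]); c1 <- min(fg[, 2]); c2 <- max(fg[, 2])
  off_u <- c1 - 1L; off_v <- r1 - 1L
  bin <- bin[r1:r2, c1:c2, drop = FALSE]
  if (nrow(bin) < 2L || ncol(bin) < 2L)
    bin <- rbind(cbind(bin, 0), 0)   # labelling needs >= 2x2
  lab <- label_components_8(bin)
  if (max(lab) == 0L) return(NULL)
  areas <- tabulate(lab[lab > 0])
  ok <- which(areas >= params$min_blob_area & areas <= params$max_blob_area)
  if (length(ok) == 0L) return(NULL)
  stats_of <- function(id) {
    px <- which(lab == id, arr.ind = TRUE)   # col 1 = row (v+1), col 2 = col (u+1)
    u <- px[, 2] - 1 + off_u; v <- px[, 1] - 1 + off_v
    list(centroid = c(mean(u), mean(v)), area = nrow(px),
         bbox = c(min(u), min(v), max(u), max(v)))
  }
  cand <- ok[areas[ok] == max(areas[ok])]
  if (length(cand) > 1L) {
    # tie-break: lowest (v, u) bounding corner
    corners <- t(vapply(cand, function(id) {
      px <- which(lab == id, arr.ind = TRUE)
      c(min(px[, 1]), min(px[, 2]))
    }, numeric(2)))
    cand <- cand[order(corners[, 1], corners[, 2])]
  }
  stats_of(cand[1])
}

#' Detect the animal in a single frame
#'
#' Runs the full per-frame chain: background subtraction, adaptive
#' thresholding with optional colour gate, morphological cleanup, and
#' centroid extraction. Deterministic: identical frame and parameters give an
#' identical result.
#'
#' @inheritParams subtract_background
#' @return A blob list as in [extract_centroid()], or `NULL`.
#' @export
segment_frame <- function(frame, background, params = segmentation_params()) {
  d <- subtract_background(frame, background, params)
  b <- binarize(d, params, frame = frame)
  b <- morphological_cleanup(b, params)
  extract_centroid(b, params)
}

#' Read a frame image from disk
#'
#' PNG frames are read into the package's grey-level convention
#' (0..255 doubles, matrix `[height x width]`; colour frames keep their
#' channels in a third dimension).
#'
#' @param path Path to a PNG file.
#' @param grey Collapse colour channels to their mean?
#' @return Numeric matrix or array.
#' @export
read_frame <- function(path, grey = TRUE) {
  x <- png::readPNG(path) * 255
  if (length(dim(x)) == 3 && dim(x)[3] > 3) x <- x[, , 1:3]  # drop alpha
  if (grey) frame_grey(x) else x
}

#' Track the animal over a directory of numbered frames
#'
#' Applies [segment_frame()] to every PNG in `dir` (lexicographic order =
#' frame order). The background model is the per-pixel median of
#' `background_frames` evenly spaced frames unless one is supplied.
#'
#' @param dir Directory of numbered PNG frames.
#' @param params A [segmentation_params()].
#' @param camera_id Identifier written into the output table.
#' @param background Optional background matrix; computed from the frames
#'   when `NULL`.
#' @param background_frames Number of frames for the median background model.
#' @return The centroid table: a data.frame with columns `camera_id`,
#'   `frame`, `u`, `v`, `area`, `valid`.
#' @export
track_frames <- function(dir, params = segmentation_params(), camera_id = "A",
                         background = NULL, background_frames = 11L) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found in ", dir)
  if (is.null(background)) {
    idx <- unique(round(seq(1, length(files), length.out = min(background_frames, length(files)))))
    background <- background_model(lapply(files[idx], read_frame))
  }
  n <- length(files)
  out <- data.frame(camera_id = rep(camera_id, n), frame = seq_len(n) - 1L,
                    u = NA_real_, v = NA_real_, area = NA_integer_,
                    valid = FALSE)
  for (i in seq_len(n)) {
    blob <- segment_frame(read_frame(files[i], grey = is.null(params$colour_range)),
                          background, params)
    if (!is.null(blob)) {
      out$u[i] <- blob$centroid[1]; out$v[i] <- blob$centroid[2]
      out$area[i] <- blob$area; out$valid[i] <- TRUE
    }
  }
  out
}
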