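---
title: "Tracking a swimming animal in 3D from two cameras: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a swimming animal in 3D from two cameras: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtrack3d)
```

# The problem

Marine mammals housed in pools swim in three dimensions, and much of what is
interesting about their behaviour — diving, circling routines ("swimming
rings"), preference for particular pool zones — is invisible to a single
overhead view. `dtrack3d` reconstructs the 3D trajectory of one animal from
two synchronized wide-angle cameras mounted a few metres above the water on
opposite sides of a circular pool (the reference deployment is a 21 m
diameter, 5 m deep pool, 1280x720 px at 30 fps, cameras about 4 m above the
surface), and reduces the trajectory to behavioural summaries.

The pipeline is: camera calibration → per-frame blob detection in each view
→ pixel-track smoothing → two-ray triangulation with refraction correction
→ outlier filtering → analytics. A synthetic-scene generator drives every
stage in closed loop, which is how the package validates itself without
footage of a real animal.

# Camera model

Each camera is a pinhole with radial–tangential lens distortion. A world
point $X$ maps to normalized coordinates $x' = x/z$, $y' = y/z$ after the
rigid transform $x_\mathrm{cam} = R X + t$, is distorted by

$$x_d = x'(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2p_1 x' y' + p_2(r^2 + 2x'^2),
\qquad r^2 = x'^2 + y'^2,$$

(symmetrically for $y_d$), and lands on the sensor at $u = f_x x_d + c_x$,
$v = f_y y_d + c_y$. The default intrinsics ($f_x = f_y = 654.55$,
$c_x = 1279/2$, $c_y = 719/2$) and the five distortion coefficients
$(k_1, k_2, p_1, p_2, k_3) = (-0.335, 0.120, 0, 0, -0.020)$ are the
calibrated values for the reference wide-angle cameras; the principal point
implies 0-based pixel indexing of the 1280x720 sensor. Pixels convert back
to viewing rays by inverting the intrinsic map, undistorting (fixed-point
iteration, cap 100 iterations, tolerance $10^{-10}$), taking the
camera-frame points at depths $z=0$ and $z=1$, and mapping both through the
inverse pose.

Strongly negative $k_1$ polynomials are only invertible up to a finite
radius (about $r = 0.9$ for the default coefficients, while the sensor
corners sit near $r = 1.1$). The camera-model functions guard this — the
fixed-point inversion fails loudly outside the invertible region — and the
*synthetic* rig therefore defaults to a milder model
($k_1 = -0.12, k_2 = 0.02$) that is invertible across the whole sensor, so
closed-loop tests are exact everywhere. All tolerances and coefficients are
configurable per camera.

## Pose estimation

Camera pose is estimated from at least five surveyed landmarks
(world coordinates measured in the pool, pixel positions clicked in each
view) with RANSAC around a Perspective-n-Point solve. Samples of six
correspondences are fitted by DLT and refined by Levenberg–Marquardt on the
reprojection error (rotation parameterized as a Rodrigues vector); with
exactly five points the refinement is initialized from a coarse orientation
grid (Euler angles in 30° steps, translation solved linearly given the
rotation). Defaults: 200 iterations, 5 px inlier threshold, seeded sampler;
the final pose is refit on the full consensus set. With noiseless input all
points are inliers and the result is seed-independent.

# Segmentation

The animal is found per frame by background subtraction: the absolute
difference against a static median background (the reference deployment
re-tuned parameters per session, since the background depends on natural
light), masked to the tracking area. A pixel is foreground iff its
difference exceeds the *local mean* over an `adaptive_block` window
(default 101 px, computed exactly with an integral image) plus
`adaptive_offset` (default 10 grey levels), with an optional per-channel
colour gate on the original frame. The offset raises the threshold — a flat
zero image yields no foreground. Erosion then dilation with disc elements
(default radius 2) removes speckle; 8-connected components outside the blob
area bounds (default 200–50 000 px for 1280x720 — an engineering default)
are discarded and the largest survivor's area-weighted centroid is the
observation. Area ties break to the lowest (v, u) bounding corner. Absence
of a blob is a value, not an error. The chain is deterministic and the
colour gate is applied alongside the threshold (the original order is not
documented; this is a package choice).

# Reconstruction

## Pixel smoothing

Centroid series are smoothed per camera with a Gaussian kernel
(default $\sigma = 32$ frames ≈ 1 s; truncated at $4\sigma$), applied
independently to each contiguous run of detections. Boundaries use **odd
(point-mirrored) reflection**, which continues the local trend: an even
mirror turns every segment end into a local extremum, dragging the first
and last $\sigma$-worth of frames toward a standstill, biasing speeds and
systematically under-accumulating azimuth (by about $2\sigma\omega$ rad for
a circuit at angular rate $\omega$) — enough to lose the final swimming
ring of a session. Odd reflection reproduces affine signals exactly,
including at the boundary; in exchange, boundary samples may slightly
exceed the min/max of their neighbourhood, which we consider the right
trade-off for kinematics.

## Triangulation and refraction

Matched centroids back-project to two rays. Because the rays are generically
skew, their "intersection" is the midpoint of the common perpendicular, and
the length of that segment is kept as a per-frame quality score (`gap_m`).
Rays closer than 0.5° to parallel are rejected.

The world frame has its origin at the pool centre on the water surface with
z pointing down (depth in metres). If the unrefracted midpoint falls below
the surface, both rays are refracted at the flat interface $z = 0$ by
Snell's law, $\sin\theta_\mathrm{air} = n \sin\theta_\mathrm{water}$, with
azimuth preserved, and the midpoint is recomputed on the underwater
segments. The default effective index is 1.4 — the value calibrated against
known in-pool distances in the reference deployment rather than the
textbook 1.33; the effective value also absorbs residual camera-model error
and is configurable. The synthetic projector solves the same physics
forward (1-D root find on the Snell condition along the camera-to-point
horizontal line, tolerance $10^{-13}$ on the crossing parameter), so
reconstruction inverts it to numerical precision.

## Outlier filtering and gaps

For each coordinate series and for the inter-frame displacement series we
compute type-7 quartiles, the IQR, and Tukey's outer fences
$Q_1 - 3\,\mathrm{IQR}$ / $Q_3 + 3\,\mathrm{IQR}$; frames beyond a fence
("major outliers") are invalidated, with the cause recorded per frame.
Coordinates are tested on both sides. Displacement is tested only against
the upper fence — a small displacement is ordinary behaviour, a still
animal is not an artifact, and a two-sided test would discard the
smoothing-attenuated boundary frames of any near-constant-speed swim — and
a frame is flagged only when *both* its incoming and outgoing jumps are
outlying: a tracking glitch teleports the detection away and back, while
the innocent frame after a glitch shares just the return jump. This also
keeps the filter idempotent on degenerate (near-constant-displacement)
series. Inner fences ($1.5\,\mathrm{IQR}$) are computed but only the outer
ones discard. Gaps of
up to 30 frames (1 s) are then filled by linear interpolation and flagged;
longer gaps stay invalid.

# Analytics

*Speeds.* Per-frame speed is the Euclidean displacement between consecutive
valid frames divided by the frame interval (33.33 ms at 30 fps).
Interpolated frames carry speeds but are excluded from the maximum. The
speed range $[0, v_{max}]$ splits into three equal-width bands — for
$v_{max} = 5.1$ m/s the boundaries are 1.7 and 3.4 m/s. These printed
boundaries are equal-width thirds, not empirical tertiles; a data-tertile
mode (`mode = "data"`) is available.

*Zones.* Depth is tested first: anything deeper than `shallow_max_depth`
(default 1.4 m) is **Bottom**. Otherwise a position over the deep-floor
footprint polygon is **Deep Area**, else **Shallow Area**; every valid
frame gets exactly one label. The default footprint is a centred 64-gon of
radius `diameter/3` — a central deep bowl — standing in for the surveyed
polygon of a real pool, which should be supplied in the pool configuration.

*Rings.* A swimming ring is one complete circuit: the cumulative unwrapped
azimuth about the ring centre (default: centroid of the deep footprint)
changing by $2\pi$ in either direction. Boundaries are the crossings of
$j \cdot 2\pi$ relative to the fixed start azimuth — the frame that
completes a ring starts the next. (Re-zeroing at each noisy, discretely
sampled crossing would accumulate the per-ring overshoot and starve the
final circuit of its closing fraction.) Spans with mean horizontal radius
under 2 m (pivoting, not circuits) are rejected. A circuit within `end_tolerance` (0.1 rad ≈ 1.6% of
a turn) of closure at the last frame counts as complete — a session holding
exactly k turns plus symmetric noise would otherwise lose its final ring to
a coin flip. Because "the distance between start and end" of a closed loop
is near zero by construction, ring size is reported both as start–end
distance and as path length (with mean radius and mean speed).

# The synthetic scene generator

The generator emulates the reference conditions: a 21 m/5 m pool, two
1280x720, 30 fps cameras at 4 m height on opposite sides (radius 11 m,
aimed at mid-depth pool centre). Motion is piecewise: circles (the
dominant observed routine), sinusoidal dives, and dwells with truncated
Gaussian jitter. Ground truth bookkeeping — ring schedule, zone labels,
speeds — is recorded from the generating equations. Projection uses the
full camera model, optionally through the refractive interface, with seeded
Gaussian pixel noise; rendering places a constant-contrast ellipse
(default semi-axes 35x14 px, roughly a 2.5 m animal at typical range) on a
static background with optional grey noise.

What the generator does *not* emulate: surface ripple and glare, caustics,
occlusions, appearance change with depth, non-rigid body shape, lighting
drift. Passing closed-loop tests therefore demonstrates the geometry,
filtering and analytics are correct, not that segmentation parameters
transfer to arbitrary real footage — parameter tuning per session remains a
manual step, as in the original workflow.

# Numerical choices and problem sizes

Undistortion: fixed-point, cap 100, tol $10^{-10}$, failure is an error
naming the point. Triangulation: parallel threshold 0.5°. Quantiles: type 7
(linear interpolation). Ring closure: $2\pi - 10^{-9}$ interior,
$2\pi - 0.1$ at end of data. RANSAC: 200 iterations, 5 px, seeded. All
randomness in a run flows from a single seed, and every CSV/JSON output is
byte-reproducible under a fixed seed.

The validation suite uses synthetic sessions of ~1000 frames for geometric
closed loops, five jittered multi-ring sessions (radii 3–8 m, both
directions), 300 rendered 1280x720 frames for the noiseless segmentation
loop and 60 for the noisy one, sizes chosen to exercise every code path at
full sensor resolution while keeping the whole suite quick to run.

# Known limitations

- Two cameras only; no bundle adjustment, no rolling-shutter model, no
  full fish-eye (equidistant) projection — the polynomial model loses
  invertibility at extreme field angles.
- The flat-interface refraction model ignores waves; surface chop adds
  unmodelled noise that the smoothing and fences must absorb.
- Frame-index alignment between cameras is assumed (a per-camera frame
  offset is configurable, but sub-frame sync is not modelled).
- Zone and ring definitions assume a roughly circular pool with a single
  deep region.
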