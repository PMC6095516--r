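# dtrack3d

Semi-automatic 3D video tracking of a large aquatic animal — a dolphin in
the reference deployment — in a circular pool, from two synchronized
wide-angle cameras, with behavioural summaries of the reconstructed
trajectory. For behavioural scientists and facility staff who have two
fixed cameras over a pool and want per-session 3D trajectories, zone
occupancy, speed profiles and swimming-circuit ("ring") statistics without
instrumenting the animal.

## Method

Each camera is a pinhole with radial–tangential distortion: a world point
projects through `x' = x/z, y' = y/z`, the distortion polynomial
`x_d = x'(1 + k1 r² + k2 r⁴ + k3 r⁶) + 2p1 x'y' + p2(r² + 2x'²)`, and
`u = fx·x_d + cx, v = fy·y_d + cy`. Camera poses come from ≥ 5 surveyed
landmarks via RANSAC Perspective-n-Point. Per frame, the animal is detected
in each view by background subtraction, adaptive thresholding, and
morphological cleanup; the blob centroids (Gaussian-smoothed, σ = 32
frames) back-project to viewing rays, which are refracted at the water
surface by Snell's law (`sin θ_air = n · sin θ_water`, effective n = 1.4)
when the target is submerged, and triangulated as the midpoint of the
common perpendicular. Tukey outer fences (3·IQR) discard major outliers.
Analytics classify every frame into Deep Area / Shallow Area / Bottom
(depth threshold 1.4 m), compute speeds (three equal-width bands of
`[0, v_max]`), and detect complete circuits by 2π accumulation of the
unwrapped azimuth.

A synthetic-scene module generates ground-truth trajectories, projects
them through the same camera/refraction model, and renders simple frames,
so the whole pipeline is testable end to end without real footage.

## Worked example

Simulate a short session (one 5 m-radius circuit), render frames, track
them, and summarize:

```r
library(dtrack3d)

cfg <- scene_config(seed = 7)          # 21 m pool, two cameras at 4 m height
sim <- run_simulation(cfg,
  segments = list(list(type = "circle", centre = c(0, 0), radius = 5,
                       turns = 1, duration_s = 10, depth = 1.2)),
  out_dir = "session", render = TRUE)

rc <- run_config(frames_dir_a = sim$frame_dirs[["A"]],
                 frames_dir_b = sim$frame_dirs[["B"]],
                 cameras = cfg$cameras, pool = cfg$pool,
                 fps = 30, smoothing_sigma = 2, out_dir = "session/out")
res <- run_tracking(rc)

res$counts
#> $frames_detected_a   301
#> $frames_detected_b   301
#> $frames_triangulated 301
#> $frames_filtered     0
#> $frames_interpolated 0
#> $frames_valid_final  301

res$summary$rings[, c("duration_frames", "duration_s", "path_length_m",
                      "mean_radius_m")]
#>   duration_frames duration_s path_length_m mean_radius_m
#> 1             300         10      31.39107      4.996109
```

Every detected frame triangulated, none filtered; the single circuit is
recovered with its duration (300 frames = 10 s at 30 fps), path length
(≈ 2π·5 m) and mean radius. `session/out/` holds the centroid CSVs, the
trajectory CSV (`frame, time_s, x_m, y_m, z_m, gap_m, valid,
interpolated`), `rings.csv`, and `summary.json` with zone occupancy and
speed-band times. A thin CLI wrapping these functions is installed at
`inst/scripts/dtrack` (`calibrate`, `track`, `analyze`, `simulate`).

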