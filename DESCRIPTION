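Package: dtrack3d
Title: Semi-Automatic 3D Video Tracking of a Large Aquatic Animal from Two Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional swimming trajectories of a single
    large aquatic animal (e.g. a dolphin) in a pool from two synchronized
    wide-angle camera views. Implements a pinhole camera model with
    radial-tangential lens distortion, RANSAC Perspective-n-Point pose
    estimation from surveyed landmarks, background-subtraction blob tracking,
    two-ray triangulation with air-water refraction correction (Snell's law at
    a flat interface), Tukey-fence outlier filtering, and trajectory analytics:
    pool-zone occupancy, speed categories, and detection of complete swimming
    circuits ("rings"). A synthetic scene generator renders ground-truth
    trajectories through the same camera model so that every pipeline stage is
    testable without real footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
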