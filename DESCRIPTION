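Package: gaitkin
Title: Fish Swimming Kinematics from High-Speed Silhouette Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts swimming-gait kinematics of a single fish from
    high-speed flow-tunnel video. Frames are segmented (contrast
    stretching, Gaussian smoothing, motion clipping, Otsu thresholding,
    blob selection), the body midline is recovered by Zhang-Suen thinning
    and parameterized by four equidistant points, and per-frame
    inter-segment angles and tail-beat amplitude are summarized into mean
    tail-beat frequency, half-cycle curvature, and amplitude endpoints
    with per-frame validity checks and a whole-video acceptance rule. A
    ground-truthed synthetic generator of undulating fish silhouettes
    supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    signal,
    zoo,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
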