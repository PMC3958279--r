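Package: depthfall
Title: Fall Detection from Top-View Depth-Camera Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human falls in sequences of overhead (ceiling-mounted)
    depth-camera frames.  Implements the full processing chain: floor
    clamping and sensor-dropout filling, reference-frame foreground
    extraction with depth-level slicing, Sobel edge carving, super-pixel
    binarization, a run-based connected-component blob labeler,
    anthropometric person identification (head-ground gap, head-shoulder
    gap, head dimensions), fusion-aware multi-person tracking, and a
    400 mm floor-proximity fall rule.  A synthetic top-view depth-scene
    simulator with per-frame ground truth makes the whole pipeline
    testable without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
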