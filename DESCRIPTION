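Package: srtkit
Title: Lazily Loadable Sample Folders for Spatially-Resolved Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts large multi-channel microscopy images and
    spatially-resolved transcriptomics outputs (Space Ranger-style Visium
    folders, Vizgen-style MERFISH tables) into self-describing sample
    folders that can be loaded lazily: tiled multi-resolution image
    pyramids in a cloud-optimized TIFF layout, per-feature sparse vectors
    independently deflate-compressed behind a byte-offset index, point
    overlays in plain CSV, and a deterministic JSON manifest. Includes a
    byte-range reader abstraction with fetch accounting, annotation
    import/export (points, circles, polygons) with geometric label
    assignment, deterministic synthetic fixture generators for offline
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    jpeg,
    tiff,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    curl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
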