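Package: mmd
Title: Multimodal Multiphoton Microscopy Analysis of 3D Cellular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable analysis toolkit for co-registered multimodal
    multiphoton time-lapse imaging of tissue, built around three analyses:
    threshold-based 3D cell segmentation with nearest-neighbour centroid
    tracking and motility statistics (instantaneous velocity, total
    displacement, migration direction, population curves); cell-centered
    quantification of local collagen fiber alignment from second harmonic
    generation (SHG) images via the eccentricity of an ellipse fitted to the
    thresholded 2D Fourier magnitude; and area-based NADH fluorescence
    lifetime (FLIM) statistics over user- or randomly-selected regions.
    Includes TIFF stack I/O with a shared region-of-interest contract across
    modalities, grid mosaic assembly, a tile exporter for external fiber
    extraction tools, a ground-truthed synthetic scene generator (migrating
    cells, oriented fiber fields, two-region lifetime maps), and an
    end-to-end deterministic pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
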