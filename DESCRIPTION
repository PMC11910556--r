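Package: SargassumRafts
Title: Spectral Detection and Vectorization of Floating Sargassum Rafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects floating Sargassum rafts in Sentinel-2-style L2A
    surface-reflectance imagery of the Caribbean using a calibrated
    five-condition spectral band rule, computes the Floating Algae Index
    (FAI) for Landsat-style bands, masks clouds with Sen2Cor scene
    classification codes, removes noise by local-entropy and
    minimum-component-size filtering, vectorizes detections into
    attributed raft polygons (area, distance to coast, ocean/beach/other
    seaweed class), derives sandy-beach masks from multi-epoch cover
    stacks, and summarises scenes (total raft area, cloud percentage,
    recent-pass tables, attribute queries). Includes a seeded synthetic
    multispectral scene generator with exact ground truth so the whole
    pipeline is testable end to end without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, tiff, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
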