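Package: pushscope
Title: Pushing-Force Microscopy and Actin-Pool Coordination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for confined immune-cell migration imaging:
    pushing-force microscopy from embedded-bead Z-kymographs (Otsu edge
    tracking with sub-step interpolation), K-means classification of which
    cell compartment (none, cytoplasm, central actin pool, nucleus) drives
    substrate deformation, 2D cell morphometry (segmentation, nearest-centroid
    tracking, speed, protrusion decomposition, intensity ratios, MTOC-first
    orientation, retraction-event pooling), normalized lagged cross-correlation
    with circular-shift permutation significance, constriction actin-density
    ratios, and deformation/actin local-maxima proximity.  A fully
    ground-truthed synthetic microscopy generator emulates every assay
    geometry so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
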