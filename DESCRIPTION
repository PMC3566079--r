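Package: dentexture
Title: Dental Surface Texture and Microwear Analysis for Controlled
    Feeding Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying dental wear from gridded occlusal
    height maps and 2D microwear feature tallies. Implements the ISO
    25178-style processing chain (areal Gaussian S-filter, polynomial
    form removal, L-filter) yielding primary, S-F and S-L surfaces, a
    full set of areal surface-texture parameters (height, spatial,
    hybrid, functional and motif-segmentation families), standard
    pit/scratch microwear counts in a fixed counting square, robust
    heteroscedastic group statistics (Welch-Yuen omnibus on trimmed
    means, pairwise Yuen tests with studentized-maximum-modulus
    adjustment, Cliff's rank-based method, and a dual-significance
    rule), and forward-stepping canonical discriminant analysis with
    group-centroid confidence ellipses. A calibrated synthetic-surface
    generator emulates a four-diet rabbit feeding experiment so the
    whole pipeline can be exercised and validated without confocal
    scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    EBImage,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
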