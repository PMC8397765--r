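Package: tomoqc
Title: Image-Quality Metrics and Phase Retrieval for Propagation-Based Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-quality analysis for phase-contrast
    synchrotron micro-tomography of fibrous soft tissue. Provides a
    synthetic phantom generator emulating tendon volumes (parallel
    collagen-scale fibers in a darker matrix, fat-cell spheres), a
    wave-optics stage (first-fringe distance rule, flat/dark correction,
    paraxial Fresnel forward propagation, Paganin single-distance phase
    retrieval with a configurable delta/beta ratio, skin-dose arithmetic),
    four volumetric quality metrics (power-spectral-density spatial
    resolution, fiber-to-matrix contrast ratio, uncertainty of
    threshold-based segmentation, gradient sharpness at edges) with
    reproducibility summaries, and cross-sectional morphometry
    (reorientation, sub-volume extraction, maximum-intensity-projection
    area measurement). Volumes are exchanged as multi-page TIFF stacks
    with JSON sidecars; reports as CSV plus JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    EBImage,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
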