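Package: serialreg
Title: Serial Histology Section Registration and 3D Stack Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registration of ordered serial histology sections into a common
    3D stack. Consecutive section pairs are aligned by rotation-aware keypoint
    matching with a built-in corner detector and patch descriptors, robust
    affine estimation via RANSAC, and B-spline free-form non-rigid refinement
    driven by a local normalized cross-correlation loss with diffusion
    regularization of the displacement field. Per-pair transforms are composed
    into a common anchor frame so that every slice is resampled exactly once.
    Includes a landmark-based evaluation suite (relative target registration
    error and its aggregates, registration robustness), a synthetic
    serial-section generator with exactly tracked landmarks and ground-truth
    transforms, readers and writers for PNG and baseline TIFF stacks, landmark
    CSV tables and JSON transform files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
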