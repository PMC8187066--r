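Package: resl0
Title: Sparse-View Photoacoustic Image Reconstruction by Regularized
    Smoothed-L0 Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compressed-sensing reconstruction of photoacoustic tomography
    images from sparse-view, frequency-domain pressure data. Implements the
    temporal-frequency forward model for a circular scan geometry, an
    orthonormal periodized Daubechies wavelet sparsity basis, the smoothed-L0
    (SL0) solver with exact feasibility projection, and the error-tolerant
    regularized smoothed-L0 (ReSL0) solver whose Tikhonov-regularized
    projection and adaptively chosen regularization parameter tolerate
    measurement noise. Ships procedural test phantoms (Shepp-Logan,
    vessel-like, resolution bars), PSNR/NMAE image-quality metrics, and a
    seeded experiment runner for view-count and noise sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
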