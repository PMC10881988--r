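Package: prmsrs
Title: Penalized Reference Matching for Hyperspectral Raman Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every pixel spectrum of a hyperspectral stimulated Raman
    scattering (SRS) stack against a library of pure-compound reference
    spectra using a shift-penalized cosine similarity, producing per-pixel
    similarity-score maps bounded in [0, 1]. Includes the full spectral
    preprocessing chain (arPLS baseline correction, common-grid linear
    interpolation, min-max and Euclidean normalization), a Moore-Penrose
    pseudo-inverse linear unmixing baseline for comparison, downstream image
    products (ratiometric maps, channel merges, threshold masks,
    top-percentile spectrum extraction, structural-similarity agreement
    metrics), four-Gaussian decomposition of CH-stretching-region reference
    spectra, and a seeded synthetic-fixture generator for spectra and stacks
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
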