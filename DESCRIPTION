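Package: spinetrack
Title: Longitudinal Dendritic Spine Morphometry from Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis engine for longitudinal two-photon/confocal
    imaging of dendritic spines. Registers time-series z-stacks with subpixel
    DFT phase correlation and local normalized-mutual-information ROI
    tracking, detects spine candidates with a determinant-of-Hessian blob
    detector and a small convolutional patch classifier, segments the
    dendritic shaft and spine heads (seeded watershed plus graph-based
    cluster refinement), extracts 3D spine-neck paths with a multi-stencil
    fast-marching geodesic solver and a length/complexity/smoothness path
    cost, and quantifies spine-head volume (integrated fluorescence
    intensity and FWHM sphere model) and neck length over time. Includes a
    synthetic dendrite simulator (Poisson-placed synapses, two-state Markov
    spine turnover, Gaussian PSF, Poisson noise) so the whole pipeline can
    be exercised without microscope data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
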