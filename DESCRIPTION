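Package: tactovis
Title: Cross-Modal Suppression in Mouse V1: Rate-Model, Whisker-Array
    Geometry and Spatial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tacto-visual integration in the mouse
    primary visual cortex (VISp). Implements a two-population
    (pyramidal / fast-spiking) threshold-linear rate model of
    feedforward-inhibition-mediated cross-modal suppression with its
    closed-form steady states and inhibition-stabilized-network (ISN)
    regime analysis; a 3D mouse whisker-array simulator with
    retraction/protraction, whisking-plane and roll scenarios,
    eye-centered spherical coordinates, visual-field overlap and tip
    uncertainty propagation; and spatial statistics for brain-wide cell
    position data (PCA parcellation, Gaussian kernel density maps,
    barrel-wise permutation enrichment tests, visual-space assignment).
    Seeded synthetic-data generators provide all inputs with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
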