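Package: jamscope
Title: Collective Dynamics and Jamming Analysis of Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective cell migration and the jamming transition
    in epithelial monolayers from time-lapse microscopy. Implements multi-pass
    FFT cross-correlation particle image velocimetry (two passes, 64 then 32
    pixel interrogation windows at 50% overlap), grid-seeded trajectory
    integration through velocity fields, mean-squared displacement, the
    self-overlap order parameter Q, and instantaneous RMS velocity; per-cell
    morphometry (shape index q = perimeter/sqrt(area) with a Crofton
    perimeter estimator, aspect ratio) and jamming classification against the
    vertex-model threshold p0 = 3.813; small assay arithmetic (TEER
    normalization, fluorescence per cell, elastic modulus from shear storage
    modulus); and an active-Brownian-particle monolayer simulator with image
    rendering and Voronoi label masks that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
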