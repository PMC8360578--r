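Package: morphocell
Title: Phase-Field Simulation and Feature-Space Mapping of Migrating Cell
    Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 2D crawling-cell morphodynamics with a phase-field
    membrane coupled to an excitable protrusion network and a mass-conserved
    bistable polarity field, and maps simulated or experimental binary cell
    masks into a low-dimensional shape space. Provides the mask normalization
    pipeline (motion alignment, area rescaling to a 25-pixel equivalent-circle
    diameter in a 64x64 frame), a convolutional shape classifier whose
    pre-softmax nodes define the feature vector, principal-component shape
    coordinates, Euclidean similarity scores against reference morphology
    classes, a synthetic geometry library, and morphodynamic analyses:
    boundary curvature and protrusion-speed kymographs, mean-square
    displacement with ballistic/diffusive crossover, and pseudopod event
    detection and statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
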