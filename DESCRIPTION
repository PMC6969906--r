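Package: ngrid
Title: Simulation and Assessment of Visual Distortion in Macular Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the visual distortion (metamorphopsia) that a
    central serous chorioretinopathy (CSR) lesion induces in the visual field,
    and for generating and analysing straight-line perimetry tests built on
    that model. Provides a closed-form radial displacement map for spherical
    and spherical-cap retinal lesions, SVG straight-line test-frame generation
    and rasterization, simulation of distorted percepts for vector patterns
    and raster images, a deterministic synthetic patient responder, and a
    response-collapse pipeline that reduces good/bad response logs to
    normalized heatmaps, a distortion-percentage statistic, and lesion
    location estimates. Includes a command-line interface for reproducible
    test generation, simulation, and heatmap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
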