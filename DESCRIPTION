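Package: shadowcount
Title: Lens-Free Shadow-Imaging Cell Counting and Viability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Reagent-free cell counting and viability analysis for lens-free
    shadow (in-line diffraction) images. Implements 16-region adaptive
    binarization, 3x3 matrix-expansion clustering with size-based noise and
    doublet rules, peak-to-peak-distance (PPD) viability classification,
    concentration conversion and the standard error-rate and coefficient-of-
    variation benchmarking statistics, together with a synthetic
    diffraction-scene generator with per-object ground-truth manifests so the
    whole pipeline can be validated without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
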