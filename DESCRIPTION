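Package: specmite
Title: Unsupervised Spectral-Spatial Recognition of Mite-Stressed Vegetation
    in Hyperspectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An unsupervised pipeline for recognizing pest-stressed vegetation
    (e.g. spider-mite infested jujube canopies) in UAV hyperspectral
    reflectance cubes. Provides four spectral feature constructors (principal
    components, locally linear embedding, spectral-sensitivity band selection,
    and correlation-based band clustering via automatic subspace partition),
    weighted spatial-spectral mean filtering, three pixel clusterers (K-means,
    fuzzy C-means, density-peak clustering), optimal cluster-to-class mapping,
    and thematic-map accuracy statistics (overall accuracy, kappa, producer and
    user accuracy). Includes ENVI-style cube I/O, NDVI/Otsu background masking,
    and a synthetic-scene generator that reproduces the healthy/infected/ground
    spectral contrast so every stage is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
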