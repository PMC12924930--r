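Package: tilgraph
Title: Spatial Graph Features of Tumor-Infiltrating Lymphocytes and
    Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a 371-feature catalogue of spatial statistics
    (Delaunay, Voronoi, minimum spanning tree, density, hierarchical
    density-based clustering, and lymphocyte frequency) from cell
    centroids within a tumor bed, aggregates core-level features to the
    patient level under seven schemes, and trains multiparametric
    clinical, graph, and probability-ensemble classifiers to predict
    pathological complete response to neoadjuvant systemic therapy.
    Includes point-process simulators (complete spatial randomness,
    Thomas cluster, hard-core inhibition) and cohort generators so the
    whole pipeline is testable without patient data, plus an image front
    end (Otsu foreground, tiling, Macenko stain normalization) and
    DeLong-based ROC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    FNN,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
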