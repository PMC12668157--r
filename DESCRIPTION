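Package: geocyto
Title: Geographic Embedding and Spatial Neighborhood Analysis for
    Multiplexed Imaging Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps pixel-coordinate cell centroids from multiplexed
    whole-slide imaging onto a geographic coordinate system with bounded
    Earth-curvature distortion, and analyses cellular neighborhoods with
    geodesic primitives: great-circle within-radius pair enumeration,
    per-cell neighbor counting, and density-based (DBSCAN) spatial
    clustering. Also provides marker-intensity phenotype gating,
    k-nearest-neighbor spatial marker correlation, a tidy long-format
    single-cell expression store with total-count log1p normalization,
    and provenance-based cohort construction over clinical and
    biospecimen metadata tables (organ roll-up, multimodal assay
    matching, precancer union queries, download-manifest generation).
    Seeded synthetic-data generators emulate every input schema with
    planted ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    mclust
Config/testthat/edition: 3
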