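Package: flarediary
Title: Flare Episode Segmentation and Phenotype Clustering for Daily
    Symptom Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for daily self-reported symptom diaries in
    relapsing-remitting rheumatic disease, built around axial
    spondyloarthritis flare tracking on a 5-point Likert scale. Reconstructs
    flare episodes from daily flare reports using a single-missing-day
    bridging rule, derives per-participant flare-on versus flare-off symptom
    profiles with paired t-test inference, and clusters participants into
    flare phenotypes with a from-scratch affinity propagation implementation
    (negative squared Euclidean similarity, quantile-based preference). A
    fully parameterized synthetic cohort generator with planted phenotype
    clusters, alternating flare/non-flare dynamics and missing data makes
    every stage testable without access to patient data.
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
    mclust
Config/testthat/edition: 3
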