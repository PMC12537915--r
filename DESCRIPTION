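Package: graphMCDM
Title: Hybrid Multi-Criteria Decision Analysis with Distance-Correlation
    Weighting and Graph-Seeded k-Means
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds composite performance indices from a decision matrix of
    alternatives evaluated on multiple criteria. Criterion weights are
    computed objectively with the distance-correlation variant of the CRITIC
    method (DCRITIC), alternatives are scored and ranked with the WASPAS
    weighted sum/product aggregator, and alternatives are grouped with a
    k-means procedure whose initial centroids are selected deterministically
    from a spectral embedding of a Gaussian similarity graph. A robustness
    harness re-runs the pipeline under alternative normalizations (fuzzy
    quantization, decimal scaling, vector), weightings (entropy, MEREC) and
    aggregators (TOPSIS, VIKOR) and quantifies rank agreement (Spearman) and
    group agreement (V-measure). Score-deconstruction and change-decomposition
    analytics attribute composite scores, and their change over time, to
    individual criteria. Includes seeded synthetic decision-matrix generators
    and transcriptions of the published country score, rank and group tables
    of an Organization of American States road-safety benchmarking study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
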