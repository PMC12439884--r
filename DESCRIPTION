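Package: spotMosaic
Title: Stitching, Spatial Pattern Consensus and Factor Transfer for
    Multi-Array Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatial transcriptomics experiments in which a
    single tissue section spans several hexagonal capture areas.
    Implements landmark-based rigid alignment and stitching of capture
    areas onto a donor-level artificial spot grid, detection and
    resolution of overlapping spots, spot- and nucleus-level quality
    control and normalization, Moran's I spatial pattern detection with
    cross-donor consensus grouping, one-vs-all t-statistic registration
    across datasets and species, non-negative matrix factorization with
    projection of factors onto spatial data, ligand-receptor
    co-occurrence enrichment from spot deconvolution weights, and
    model-selection statistics (BIC, Rand index, overlap concordance).
    A synthetic data module generates Visium-like multi-array layouts
    with planted ground truth so every stage can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
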