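Package: dspmacro
Title: Spatially Resolved Macrophage Signature Analysis for Digital Spatial Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving and evaluating spatially resolved
    macrophage gene signatures from GeoMx-style digital spatial profiling (DSP)
    experiments. Covers AOI and gene quality control with negative-probe limits
    of quantitation, third-quartile (Q3) normalization, batch harmonization,
    mask validation by Kolmogorov-Smirnov enrichment, empirical-Bayes moderated
    t-test differential expression with duplicate-core handling, signed and
    significance-weighted signature derivation with a B-cell contamination
    filter, patient-level weighted signature scoring with tertile survival
    stratification (Kaplan-Meier, log-rank, Cox proportional hazards), category
    association by Fisher exact tests, hypergeometric gene-set enrichment, and
    single-cell module scoring. Includes a synthetic-data generator that plants
    known differential expression, batch structure, duplicate cores, and
    survival effects so that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
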