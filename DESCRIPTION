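Package: heatmir
Title: Heat-Stress Response Phenotyping of Dairy Cows from Milk Mid-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for building a milk Fourier-transform
    mid-infrared (FT-MIR) prediction of individual heat-stress response in
    dairy cows: temperature-humidity index (THI) computation from hourly
    weather, random-regression test-day modelling by Henderson's mixed-model
    equations with a pedigree-based relationship inverse, rule-based
    reference heat-stress classes from udder surface temperatures and
    standardized milk-trait residuals, spectral preprocessing (gap-5 first
    derivative, informative-region selection, correlation pre-selection),
    partial-least-squares temperature calibration and two-stage random-forest
    classification under cow-period-grouped cross-validation, a combined
    phenotype, Snell-score transformation and a population-scale mixed-model
    analysis. Includes a synthetic multi-farm herd generator with planted
    heat-stress effects so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    ranger,
    mixOmics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
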