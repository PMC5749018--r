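Package: FISHpanel
Title: Multi-Colour FISH Panel Discovery for Prostate Cancer Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering multi-marker fluorescence in situ
    hybridisation (FISH) panels that discriminate progressive from
    non-progressive prostate cancer in active-surveillance cohorts.
    Converts per-nucleus FISH signal enumerations into specimen-level
    parameters (Gain, Loss, Homozygous deletion, Ratio, Split, 2Edel),
    screens parameters against clinical covariates by Pearson correlation,
    ranks 3-6 parameter combinations by exhaustive cut-off optimisation
    under a distance-from-ideal (DFI) objective and Mann-Whitney AUC, and
    fits logistic association models with NCCN clinical risk groups,
    including risk-stratified analyses. Includes a seeded synthetic
    case-control cohort generator emulating FFPE signal truncation so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
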