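Package: gbmresist
Title: Discovery and Exploitation of Chemoradiotherapy-Resistance Drivers in
    Glioblastoma Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for deriving a chemoradiotherapy-
    resistance gene signature from survival-stratified patient cohorts and
    apoptosis-stratified cell-line panels, inferring single-cell copy-number
    profiles with a quadratic CNV score, classifying tumor subclusters by
    mean-plus/minus-SEM grouping and signature enrichment, projecting
    subcluster identities onto spatial transcriptomics spots, screening drugs
    by differential IC50 with a blood-brain-barrier filter, scoring drug
    synergy with the zero-interaction-potency (ZIP) model, and computing the
    supporting assay statistics (limiting-dilution frequency estimation,
    H-score, Kaplan-Meier/log-rank). A synthetic-data generator with planted,
    recorded ground truth replaces patient-level raw data so that every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    jsonlite,
    withr,
    pracma,
    minpack.lm,
    survival,
    limma
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
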