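Package: twinMiR
Title: Twin-Design miRNA qRT-PCR Discordance and Heritability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of miRNA qRT-PCR cycle-threshold (Ct) panels measured in
    monozygotic and dizygotic twin pairs. Implements reference-gene
    normalization to delta-Ct relative expression, within-pair expression
    discordance fold changes with low/moderate/high binning, classification of
    miRNAs into genetics-versus-environment groups from the cross-zygosity
    discordance pattern, co-twin Pearson correlation with Fisher-z pooling,
    and the Falconer twin-study heritability partition H2 = 2(rMZ - rDZ).
    Includes a variance-component twin-Ct simulator with closed-form expected
    correlations so every stage of the pipeline can be verified end-to-end
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
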