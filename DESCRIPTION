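Package: hippasym
Title: Normative Asymmetry Z-Scores for Hippocampal Subfield Volumetry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects pathological left-right asymmetry of hippocampal
    subfield volumes from automated segmentation output.  Per-region
    intra-individual right-minus-left volume differences are standardized
    against a healthy-control normative reference (packaged for two T2 TSE
    acquisition variants, or rebuilt from any healthy cohort) and flagged
    as pathological outside the 95 percent interval |z| > 2, with
    per-patient lateralization summaries.  Also provides the anatomical
    aggregation from 19 subfields to merged and combined hippocampal
    labels, readers for FreeSurfer-style subfield volume files, the paired
    statistical protocol (t-test, Wilcoxon signed-rank, Shapiro-Wilk,
    Holm-Bonferroni, Cohen's d) for comparing acquisition sequences, and a
    calibrated synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    tools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
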