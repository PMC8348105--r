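Package: septraj
Title: Trajectory Analysis of Sepsis Survivor Leukocyte Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-trajectory analysis of blood leukocyte gene expression in
    surgical sepsis survivors who either rapidly recover or develop chronic
    critical illness (CCI). Implements a control-referenced Distance From
    Reference (DFR) perturbation score, variance filtering with an
    elbow-derived cutoff, principal-component cohort geometry, and
    multi-criteria differential-expression selection with direction-concordance
    and gene-set overlap analysis. Includes a ground-truth-labelled synthetic
    cohort generator emulating the post-sepsis "genomic storm" and
    trajectory-dependent recovery, so the full pipeline is testable without
    access to patient microarray data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
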