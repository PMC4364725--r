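Package: deltabeta
Title: Paired Delta-Beta Analysis of Methylation Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality filtering, differential testing and individualized
    delta-beta classification for Illumina 450K-style beta-value matrices.
    Implements call-rate and detection p-value QC, variance filtering and PCA,
    pooled and paired t-testing with Benjamini-Hochberg adjustment, the
    per-pair delta-beta trinary classifier with recurrence filtering and
    gene-level aggregation, cross-platform concordance statistics (Pearson
    correlation and Bland-Altman limits of agreement), cross-sectional
    treated-versus-untreated comparison with per-probe regression on treatment
    duration, an IGF1 generation test summary for the clinical cohort table,
    and a logit-normal cohort simulator with planted per-individual treatment
    responses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
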