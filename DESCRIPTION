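Package: pesignal
Title: Presymptomatic Preeclampsia Signals from Maternal Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("ITU", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spike-in-anchored 5'-end UMI RNA-seq of
    maternal peripheral blood, aimed at detecting presymptomatic signals of
    late-onset preeclampsia. Provides ERCC spike-in size factors and
    normalization, negative-binomial library-bias correction, a
    squared-coefficient-of-variation fluctuation test against spike-in
    technical noise, PCA with principal-component/phenotype correlation
    screening, preranked gene set enrichment analysis on component loadings
    with direction-of-change inference, a simplified negative-binomial Wald
    differential-expression test, a per-variable logistic/ROC biomarker
    screen at a fixed false-positive rate, blood cell-type marker derivation
    and signature enrichment, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
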