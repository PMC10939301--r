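Package: mtpcor
Title: Correlation Strategy Comparison and Selection-Integration for
    miRNA-Target Pair Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects miRNA-target gene pairs (mTPs) from paired gene and
    miRNA expression matrices by computing Pearson correlations under seven
    strategies that combine individual CPM profiles with co-expression module
    eigengenes and hub profiles. Each strategy and correlation threshold is
    scored against a database of predicted/validated pairs using overall and
    per-miRNA (specific) odds ratios with one-sided Fisher's exact tests, and
    results are integrated by selecting, for every miRNA, the significant
    strategy/threshold combination with the highest specific odds ratio.
    Includes a database-subsampling protocol to assess ranking robustness and
    a seeded synthetic-data generator with planted regulatory architectures
    for offline validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
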