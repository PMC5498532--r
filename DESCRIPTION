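Package: emtscreen
Title: Pan-Cancer Discovery of Epithelial-Mesenchymal Transition Gene
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-screen pipeline for discovering epithelial/mesenchymal
    state-associated gene signatures across cancer entities: an anchor-ratio
    differential screen over cell-line compendia, a Spearman anchor-correlation
    screen over bulk-tumor cohorts, and their all-entity intersection into a
    shared signature. Includes signature scoring as average z-scored
    expression, patient stratification by k-means with Pearson-correlation
    distance, Kaplan-Meier/log-rank survival association, ROC-based biomarker
    dichotomization, and clinical association statistics. Ships a synthetic
    data generator that plants epithelial/mesenchymal marker structure,
    purity-weighted stromal contamination of bulk tumors, and outcome linkage,
    with a ground-truth record for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
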