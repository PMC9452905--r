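Package: icbsig
Title: Gene-Set Screening and Signature Construction for Immunotherapy
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for discovering transcriptomic
    signatures of immune checkpoint blockade (ICB) response in clear cell
    renal cell carcinoma. Starting from single-cell marker statistics
    (Wilcoxon rank-sum differential expression with fold-change and
    detection-rate filters), the pipeline screens enriched gene sets for
    predictiveness in a bulk cohort with a nearest-centroid classifier
    under a multiple random validation protocol, localizes predictive
    programs to cell subclusters with single-sample gene-set variation
    scores, assembles a candidate gene list, and reduces it by greedy
    leave-one-out backward elimination maximizing the area under the ROC
    curve. The resulting signature panel is validated by ROC analysis
    (Welch t p-value, Wilson confidence intervals), logistic conversion of
    prediction scores to nonresponse probabilities, and survival
    stratification (Kaplan-Meier, log-rank, maximally selected cutpoints,
    univariate Cox regression). A synthetic-data generator with planted
    marker programs, abundance shifts and survival signal provides ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
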