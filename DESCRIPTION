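Package: reogps
Title: Rank-Based Gene-Pair Signatures for Chemotherapy Response
    Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds qualitative transcriptional signatures from the
    within-sample relative expression ordering (REO) of gene pairs, in the
    spirit of the top-scoring-pairs family of classifiers.  Provides a
    synthetic-data generator with planted responder/non-responder signal,
    rank-correlation screening of response genes, expression-difference
    oriented gene-pair screening with Wilcoxon and exact-binomial filters,
    greedy forward selection of a majority-vote gene-pair signature, and
    evaluation by confusion metrics, rank-based AUC, Kaplan-Meier curves
    and Cox proportional-hazards models.  Because a sample is classified
    only from the ordering of gene pairs within its own expression
    profile, predictions are invariant to any strictly increasing
    per-sample transformation and hence robust to batch and platform
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
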