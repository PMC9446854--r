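Package: overlaprc
Title: Bayesian Genomic Prediction with Overlapping Functional Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs samplers for the BayesR family of genomic prediction
    models with functional annotation categories, including two models for
    markers carrying several overlapping annotations: a preferential
    annotation-assignment model (BayesRCpi, with posterior annotation
    inclusion probabilities) and a cumulative annotation-effect model
    (BayesRC+). Also provides BayesCpi, BayesR and BayesRC as special
    cases, genotype/phenotype/annotation readers (plain text and PLINK
    bed/bim/fam), window-based annotation construction from QTL hit
    tables, evaluation metrics (validation accuracy, posterior variance
    ranking, annotation enrichment), a full quantitative-trait and
    annotation-scenario simulator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
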