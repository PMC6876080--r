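Package: lrrgd
Title: Disease-Related Protein Identification by Bagged Logistic
    Regression with Gradient-Descent Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies proteins related to a target disease under the
    guilt-by-association hypothesis that similar diseases share related
    proteins. Candidate diseases are scored against the target by five
    ontology-based semantic similarity measures (Resnik, Lin, Wang, a
    process-similarity surrogate, and a gene functional-association
    surrogate) computed from Disease-Ontology-like and Gene-Ontology-like
    DAGs with annotation-derived information content. Retained diseases
    form a binary disease-by-protein feature matrix whose rows are
    regressed onto normalized similarity by an ensemble of feature-bagged
    ridge logistic regressions fitted by Newton's method; each model's
    protein calls are obtained by projected gradient descent on a relaxed
    protein-indicator vector initialized from known disease proteins, and
    calls are aggregated by vote thresholding. Includes a seeded synthetic
    fixture generator (toy ontologies, annotations, association tables
    with planted related proteins) so the full pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
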