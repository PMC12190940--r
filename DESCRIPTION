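Package: fuzzmoefs
Title: Explainable Fuzzy Rule-Based Classification of Clinical Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable fuzzy rule-based classifiers for clinical
    risk stratification, with preeclampsia screening as the running example.
    Clinical variables are encoded as strong triangular fuzzy partitions, an
    initial rule base is induced with a fuzzy decision tree driven by fuzzy
    information gain, and a multi-objective genetic algorithm reduces the
    rule base along the accuracy versus total-rule-length Pareto front.
    Inference is Mamdani-style with abstention when no rule fires, and
    centroid or bisector defuzzification yields a crisp risk score with a
    natural-language explanation of the fired rules. Missing clinical values
    are completed by expectation-maximization probabilistic principal
    component analysis with optional Bayesian shrinkage, and a synthetic
    cohort generator reproduces published class-conditional summary
    statistics so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
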