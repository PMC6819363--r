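Package: dtastop
Title: Stopping Criteria and Screening Simulation for Diagnostic Test
    Accuracy Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates technology-assisted screening for systematic reviews of
    diagnostic test accuracy. Ranks candidate references with an active-learning
    classifier (with a randomized-order control), continuously re-estimates
    summary sensitivity and specificity with a bivariate random-effects
    meta-analysis as relevant studies are identified, and evaluates retrospective
    and prospective stopping criteria (target recall, knee/elbow detection,
    loss/effort and found/effort slope rules, relevant-found counts, and
    displacement rules based on consecutive-estimate shifts or leave-one-out
    influence) that bound the loss in meta-analysis accuracy when screening is
    interrupted early. Includes a synthetic-review generator so the whole
    pipeline is testable without external corpora.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
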