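Package: caspa
Title: Action-Error Prediction from SDA-M Mental Representation Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural-dimensional analysis of mental
    representations (SDA-M) applied to action sequences: scoring of
    split-procedure judgments into standardized score (Z), correlation (R)
    and Euclidean distance (D) matrices, hierarchical average-linkage
    clustering with dendrogram and Newick export, and two algorithms that
    predict probable human action errors from these structures - AMPA
    (Analysis of Most Probable Actions) and CASPA (Correct Action Selection
    Probability Analysis), the latter a Boltzmann/softmax selection model
    over ACT-R-style activations. Includes evaluation statistics for
    comparing binary competence predictions against rater panels (confusion
    metrics, exact one-tailed binomial tests, phi correlations with
    Fisher-z averaging, rater screening) and a synthetic split-procedure
    simulator with a built-in kiosk task model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
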