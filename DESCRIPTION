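Package: drscreen
Title: Evaluation of AI-Based Versus Ophthalmologist Diabetic Retinopathy
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate an AI-based diabetic retinopathy (DR) grading
    system against manual ophthalmologist grading in a screening cohort:
    ordinal inter-grader agreement (Cohen's and weighted kappa with
    Landis-Koch interpretation, Spearman rank correlation), diagnostic test
    accuracy with Wald, Wilson and exact Clopper-Pearson binomial confidence
    intervals, and a cost-minimization model with one-way and two-way
    deterministic sensitivity analyses and break-even solving. Includes a
    synthetic two-grader screening-cohort generator and a reconstructed
    two-grader fixture so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
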