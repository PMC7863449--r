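Package: cmeval
Title: Two-Class Confusion-Matrix Evaluation with MCC, Informedness and Markedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating binary classifications from their 2x2
    confusion matrices. Computes the basic rates (sensitivity, specificity,
    precision, negative predictive value and their complements) and the
    multi-category metrics (Matthews correlation coefficient, balanced
    accuracy, bookmaker informedness / Youden's J, markedness, accuracy,
    F1) with explicit undefined-value semantics for degenerate matrices.
    Provides the lossless reparameterization of a confusion matrix in terms
    of sample size, prevalence, true positive rate and true negative rate;
    the prevalence-dependent predictive-value formulas and their inverses;
    numerical verification of the identities linking MCC to informedness
    and markedness; exhaustive enumeration of all confusion matrices of a
    given sample size with Pearson-correlation curves between metrics; a
    known-randomness classifier simulator; classifier ranking utilities;
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'panel-internal.R'
    'metrics-core.R'
    'reparam.R'
    'identities.R'
    'enumeration.R'
    'randomness-sim.R'
    'fixtures.R'
    'ranking.R'
    'io.R'
    'report.R'
    'cli.R'
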