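Package: AntiAngioPep
Title: Anti-Angiogenic Peptide Prediction by Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of anti-angiogenic peptides.
    Implements three peptide feature encoders (Bi-profile Bayes
    position-specific posterior probabilities at the N- and C-termini,
    composition-transition-distribution descriptors over four
    physicochemical residue groups, and low-frequency discrete Fourier
    power spectra of hydrophobicity and hydrophilicity profiles),
    Relief feature weighting with incremental feature selection, and a
    two-classifier ensemble that averages the positive-class
    probabilities of a Gaussian naive Bayes and a ridge-stabilised
    logistic regression base learner. Evaluation is by stratified
    k-fold cross-validation with sensitivity, specificity, accuracy,
    Matthews correlation coefficient, ROC curves and AUC. A synthetic
    peptide generator with configurable terminal residue enrichment
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
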