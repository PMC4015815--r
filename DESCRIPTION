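Package: distsvm
Title: Protein Remote Homology Detection with Distance-Based Residue and
    Top-1-Gram Pair Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SVM-DR and SVM-DT approaches to protein remote
    homology detection. Protein sequences (or the Top-1-gram sequences derived
    from PSI-BLAST frequency profiles) are converted into fixed-length feature
    vectors counting ordered symbol pairs at every positional offset up to a
    distance threshold d_max, giving vectors of dimension 20 + 400 * d_max.
    One-vs-rest family classifiers are trained with a linear support vector
    machine on unit-normalised count vectors; families are evaluated with ROC
    and ROC50 scores, and the explicit discriminant weight vector w = M alpha
    supports per-pair feature-importance analysis. A synthetic family
    generator with planted symbol pairs at controlled distances makes the full
    pipeline testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
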