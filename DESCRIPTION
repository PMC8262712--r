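Package: seqpka
Title: Sequence-Based Prediction of Isoelectric Points and Residue pKa Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the isoelectric point (pI) of peptides and proteins and
    the pKa dissociation constants of their ionizable residues from sequence
    alone.  Implements the Henderson-Hasselbalch net-charge model over a
    registry of published pKa sets (EMBOSS, Bjellqvist/ExPASy, ProMoST,
    Sillero, and others), differential-evolution fitting of pKa sets to
    experimentally labelled pI data, support-vector-regression stacking of
    base predictors, a separable-convolution peptide model and a kmer
    multilayer-perceptron ensemble for per-residue pKa, plus dataset
    handling (clustering, 75/25 splits, 10-fold cross-validation), the
    RMSE/MAE/r-squared/outlier metric suite, a benchmark harness, synthetic
    data generators with known generative structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
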