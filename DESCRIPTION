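Package: sohsite
Title: Sequence-Based Prediction of Cysteine S-Sulfenylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict S-sulfenylation (-SOH) of protein cysteines from
    primary sequence. Cysteine-centered 21-residue peptide windows are encoded
    with one-hot (binary), position-specific amino-acid propensity (PSAAP), or
    fourteen AAindex physicochemical property scales, and classified with a
    radial-basis-function support vector machine trained on balanced random
    subsamples of the (heavily imbalanced) negative class. Includes repeated
    stratified cross-validation with per-repeat balanced subsampling,
    sensitivity/specificity/accuracy/Matthews-correlation and ROC/AUC metrics,
    position-specific residue composition and two-sample enrichment analysis,
    a synthetic benchmark generator with planted positional motifs, and a
    command-line interface for dataset assembly, training, prediction and
    enrichment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
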