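Package: duxsig
Title: DUX4 and DUX4c Target Signatures, Single-Sample Activity Scores and
    Signalling Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the transcriptional programme of the DUX4
    and DUX4c double-homeobox transcription factors from perturbation panels
    of the kind used to model facioscapulohumeral muscular dystrophy (FSHD).
    Implements per-construct empirical-Bayes moderated-t differential
    expression against a common control, cross-construct concordance
    filtering to derive up/down target-gene signatures, a single-sample
    biomarker score contrasting up- and down-signature expression,
    signalling entropy (the entropy rate of a mass-action random walk on a
    protein-interaction network weighted by sample expression), and
    Fisher-exact gene-set enrichment with Benjamini-Hochberg correction.
    A synthetic-data generator with planted construct-consistent effects and
    random connected interaction networks makes the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
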