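Package: tfmars
Title: Predictive Models of Transcript Levels from Quantitative TF
    Binding Signal
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies transcription-factor (TF) binding on gene promoters
    from per-base ChIP-exo coverage tracks, converts RNA-seq counts to
    filtered, replicate-averaged FPKM, and models transcript levels from
    binding signal with multivariate adaptive regression splines (MARS):
    hinge-basis forward selection, GCV backward pruning, and cross-validated
    TF/spline stabilization. On top of the fitted models it provides the
    regulatory diagnostics used in condition-resolved TF studies:
    representation comparison (peak signal, peak windows, promoter sums),
    TF-importance scores, binding collinearity and substitution testing,
    additive-versus-multiplicative interaction scans, promoter-segment and
    region-extension regressions, coordinated-trio detection, and
    BIC-selected k-means clustering of normalized expression with
    hypergeometric gene-set enrichment. A synthetic-data generator with
    known ground truth (collinear TF pairs, hinge and saturating effects,
    multiplicative interactions, coverage tracks with localized peaks over
    Poisson background) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
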