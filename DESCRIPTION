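Package: burialCRF
Title: Segment-Conditioned High-Order Conditional Random Fields for
    Residue Burial-State Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the per-residue burial state (buried versus exposed,
    defined by thresholding relative solvent accessibility at 0.25) of
    protein chains with a high-order conditional random field whose
    potential at each position is selected by the secondary-structure
    segment containing it: order-4 and order-3 label couplings on
    alpha-helices, order-2 couplings on beta-strands, and adjacent-pair
    couplings on coils. Provides exact forward-backward inference and
    marginal decoding, maximum-likelihood training with analytic
    gradients, parsers for DSSP output and PSI-BLAST ASCII profiles, a
    feature engine (sequence profiles, conservation, contact numbers,
    profile-based doublet features), a synthetic-data generator that
    samples labels exactly from a known model, and logistic-regression
    and chain-CRF baselines for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    rlang,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, StructuralPrediction, MachineLearning
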