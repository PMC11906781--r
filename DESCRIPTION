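Package: chemomet
Title: Chemometric Workflow for Untargeted LC-MS Cell Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible chemometric pipeline for untargeted LC-MS
    metabolomics feature tables: probabilistic quotient normalization with a
    control-group reference spectrum, log10 transformation and autoscaling;
    principal component analysis with Hotelling T-squared group ellipses,
    removal of a systematic-noise component by score-loading subtraction and
    data reconstruction; PLS-DA classification validated by repeated double
    cross-validation, permutation testing and VIP-score feature selection;
    hypergeometric pathway over-representation analysis; monoisotopic-mass,
    adduct and ppm-error annotation arithmetic with calibration-curve
    semi-quantification (LOD/LOQ); and a seeded synthetic-data generator that
    emulates a four-group cell-treatment design with technical replicates,
    pooled QC samples, a rank-one batch component and per-sample dilution.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
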