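Package: kernppi
Title: Profile-Kernel Support Vector Machines for Protein-Protein
    Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds organism-specific predictors of physical
    protein-protein interactions (PPIs) from sequence alone. Interaction
    records annotated with experimental detection methods are scored on a
    1-10 reliability scale and filtered; the retained pairs are
    redundancy-reduced with an HSSP-curve (HVAL) criterion so that no two
    training interactions share similar proteins; negatives are sampled
    at a fixed ratio under the complementary dissimilarity constraint.
    Per-protein evolutionary profiles (PSI-BLAST PSSMs, or a
    substitution-matrix pseudo-profile fallback) feed a profile k-mer
    string kernel whose features are sigma-thresholded mutation
    neighborhoods of each k-residue window; protein pairs are combined
    into a symmetric pair kernel and classified with a soft-margin SVM on
    the precomputed kernel, with Platt-style probability calibration.
    Includes repeated cross-validation with precision-recall model
    selection, whole-interactome candidate enumeration and ranking, and a
    synthetic-data generator with planted interaction motifs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    e1071,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
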