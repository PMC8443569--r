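Package: pepnet
Title: Multi-Level Peptide-Protein Interaction Prediction from Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only prediction of peptide-protein interactions at two
    levels: a binary interaction probability for each peptide-protein pair and
    per-residue binding scores along the peptide. Sequences are encoded as
    multi-channel feature profiles (amino-acid identity, secondary-structure
    combined codes, polarity/hydropathy codes, PSSM and intrinsic-disorder
    numeric tracks) and fed to a multi-channel convolutional network with
    single-head self-attention, trained with a dual masked cross-entropy
    objective. Includes homology-aware cross-validation splitting based on
    normalized Smith-Waterman similarity clustering, negative sampling at a
    configurable class ratio, rank-based evaluation metrics, and a seeded
    synthetic motif-interaction data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
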