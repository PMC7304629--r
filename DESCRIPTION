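Package: bindmode
Title: Sequence-Based Prediction of Binding-Mode Landscapes of Disordered Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, from amino-acid sequence alone, whether a disordered
    protein region folds upon binding (disorder-to-order) or remains
    disordered in the bound state (disorder-to-disorder), and how strongly
    that choice depends on cellular context. Candidate binding windows of
    5-9 residues around each residue are scored by a logistic model of
    local disorder, composition and Kyte-Doolittle hydropathy biases
    relative to 20-residue flanks; the per-residue median transition
    probability, the Shannon entropy of the binned window-probability
    distribution, and a landscape classification (disorder-to-order,
    disorder-to-disorder, polymorphic, conditional folding, disordered
    binding, continuum) are reported. Includes the logistic
    parametrisation procedure (IRLS), structure-based dataset curation
    rules (observed/missing residues, 4.5 Angstrom interface contacts,
    DOR/CDR/DDR assignment), ROC/AUC and Mann-Whitney evaluation, and
    synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
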