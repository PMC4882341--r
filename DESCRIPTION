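Package: restim
Title: Reciprocity-Based Targeting for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element forward modelling of transcranial electrical
    stimulation (TES/tDCS) and EEG with the complete electrode model on
    deterministic layered-sphere head models, and montage optimization by the
    reciprocity principle. Provides a first-order tetrahedral Galerkin solver
    for the quasi-static Poisson problem with complete-electrode boundary
    conditions, elementary injection patterns and the per-element transfer
    matrix, least-squares and linearly-constrained-minimum-variance reference
    optimizers, four reciprocity-guided electrode-selection methods (one
    source, opposite, ring, ROADSS), a suite of targeting performance metrics
    (intensity, directionality, centre-of-gravity targeting error, global and
    local focality), and closed-form multilayer-sphere oracles for
    validation. Meshes round-trip through TetGen node/ele text files and
    per-element fields export to legacy VTK.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
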