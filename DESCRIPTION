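Package: Tripitope
Title: Integrative Three-Stage Prediction of CD4 T-Cell Epitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based prediction of CD4 T-cell epitopes within an
    antigen sequence for given MHC class II and T-cell receptor (TCR)
    sequences. The method integrates three stages of the class II antigen
    presentation pathway: endosomal cleavage by cathepsins S, B, and H
    (position-specific scoring matrices built from protease cleavage
    events), peptide-MHCII presentation (12-mer candidates threaded onto
    pMHCII templates with a fixed backbone and scored with a
    distance-dependent statistical potential), and TCR recognition
    (ternary pMHCII-TCR models assembled on a template library and
    scored at the TCR-pMHC interface). Candidates are ranked by the sum
    of the two interface scores after an optional cleavage filter,
    converted to Z-scores, optionally combined with external affinity
    predictions, and intersected across TCR repertoires to produce
    consensus epitopes. Includes seeded synthetic-data generators for
    every stage and training of interface potentials from
    binder/nonbinder cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cleavage.R'
    'structio.R'
    'potential.R'
    'modeling.R'
    'pipeline.R'
    'synthetic.R'
    'io.R'
    'Tripitope-package.R'
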