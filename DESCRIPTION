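Package: hdacfunnel
Title: Comparative Structure-Based Virtual Screening for Selective
    Zinc-Chelating HDAC Inhibitors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An open, testable re-implementation of a comparative
    structure-based virtual-screening funnel for hydroxamate ("zinc
    binding group") HDAC inhibitors, built around an HDAC11 target with
    HDAC1/6/8 anti-targets.  Provides ligand-library curation
    (benzohydroxamate substructure, anionic-hydroxamate state selection,
    rule-of-five and structural-alert filtering), 3D pharmacophore
    screening with excluded volumes, zinc bidentate-chelation pose
    classification, anti-target comparative elimination, score-based
    prioritization, molecular-dynamics trajectory analysis (superposition,
    RMSD, RMSF, interaction persistence) and binding-pose-metadynamics
    style aggregate scoring (PoseScore, PersScore, CompScore).  A
    deterministic synthetic-data module generates labelled ligand
    libraries, pockets, docked poses and trajectories so that every stage
    of the funnel is testable without external downloads or commercial
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    ChemmineR,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
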