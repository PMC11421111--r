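Package: PatternSig
Title: Substructure Pattern Fingerprints, Signatures, and Scaffold-Filtered
    Virtual Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based analysis of bioactivity-focused compound
    collections with curated substructure catalogs. Substructure SMILES with
    explicitly defined hydrogens ([H]) are compiled into substructure queries
    in which written hydrogens mark unsubstitutable positions, and matched
    against compound sets under a single aromaticity perception model.
    Occurrence and flexibility-corrected fingerprints are summarised into a
    score-binned signature that partitions the catalog into primary and
    secondary positive substructures, which in turn scores and ranks
    scaffold-filtered screening libraries. Includes physicochemical dataset
    validation, a synthetic data generator with planted ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils-chem.R'
    'AllClasses.R'
    'pattern_engine.R'
    'chem_io.R'
    'descriptors.R'
    'fingerprints.R'
    'signature.R'
    'screening.R'
    'fixtures.R'
    'cli.R'
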