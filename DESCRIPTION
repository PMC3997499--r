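Package: HotspotGBSA
Title: MM-GB/SA Effective-Energy Decomposition and Hot-Spot Analysis for
    Protein Dimer Interfaces
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-point MM-GB/SA analysis of protein-protein dimer
    interfaces over conformational ensembles: per-atom force-field
    parameterization from bundled fixed-charge templates, generalized Born
    (OBC-II) polar solvation with salt screening, Shrake-Rupley solvent
    accessible surface areas, inter-partner Coulomb and Lennard-Jones
    terms, per-residue decomposition of the effective binding energy with
    ensemble statistics, hot/cold-spot classification, in silico alanine
    scanning by side-chain truncation, and a relative-burial baseline.
    Also provides assay-side analytics (melting-temperature extraction
    from thermal-shift curves, size-exclusion calibration, sequence
    properties and pairwise identity/similarity) and seeded synthetic-data
    generators (ideal helical dimers, pseudo-ensembles, melting curves,
    SEC standards) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
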