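Package: crsim
Title: Kinetic Simulation of Cellular DNA Double-Strand-Break Repair
    Under Ionizing Radiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid stochastic-deterministic simulator of the cellular
    repair system at single-cell resolution: Poisson induction of DNA
    double-strand breaks (DSBs) under ionizing radiation, repair-gene
    destruction, repair-mRNA transcription and repair-protein (RP)
    translation with saturation thresholds, DSB-protein-complex (DSBC)
    synthesis through fast/slow and first/second-order channels with
    correct-repair and misrepair outcomes, reversible dis-synthesis, and
    toxin-driven genome-stability decay. Provides dose-profile and
    parameter containers with validation, conservation-ledger checked
    integration, derived capability/activity/stability indicators with
    threshold detection, TSV/JSON export, and a command-line driver for
    constant-dose and dose-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'parameters.R'
    'dose.R'
    'damage.R'
    'enzymes.R'
    'dsbc.R'
    'integrator.R'
    'indicators.R'
    'io.R'
    'crsim-package.R'
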