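Package: northernlights
Title: Simulation and Densitometric Quantification of DNA Damage on 2D
    Strandness-Dependent Electrophoresis Gels
Version: 0.1.0
Authors@R:
    person("NLA", "Maintainers", email = "nla@example.org", role = c("aut", "cre"))
Description: Forward simulator and quantification pipeline for the Northern
    Lights Assay, a paired-sample 2D strandness-dependent electrophoresis
    method that detects and distinguishes single- and double-strand breaks,
    interstrand and intrastrand DNA crosslinks and denatured single-stranded
    DNA. Provides a molecule-level model of DNA damage (restriction
    digestion, nicking, double-strand breakage, crosslinking, apoptotic
    internucleosomal fragmentation, heat denaturation), a phenomenological
    two-dimensional electrophoretic mobility model that renders two-channel
    gel rasters with known ground truth, a densitometry pipeline (Cy5 ladder
    band detection, monotone size calibration, the five diagnostic gel
    regions, background-corrected fraction percentages, size distributions
    and apoptosis-ladder peak calling), an alkaline comet assay simulator and
    tail-moment scorer, and repair-experiment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'mobility.R'
    'render.R'
    'quantify.R'
    'molecules.R'
    'damage.R'
    'scenarios.R'
    'cli.R'
    'comet.R'
    'stats.R'
    'utils.R'
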