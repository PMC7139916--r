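Package: maldipanel
Title: Design and Quantification of Multiplexed Bead-Array MALDI
    Targeted Proteomics Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted immuno-MALDI proteomics panels in which
    antibody beads are arrayed as micro-spots and decoded by mass. Provides
    a peptide mass engine (monoisotopic and average MH+ with positioned
    modifications, stable-isotope labels, point mutations and b/y fragment
    ions), in silico proteolysis with epitope-preserving peptide selection,
    assay and panel compilation into a searchable reference-mass database,
    a seeded MALDI-TOF spectrum simulator with baseline subtraction and
    signal-to-noise peak picking, spot annotation against a panel including
    PTM-ladder labelling and SILAC pair detection, ratio-based relative
    quantification with replicate statistics, and forward/reverse spike
    calibration with replicate-rule LOD and LOQ determination.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
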