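Package: hicscape
Title: Multi-Scale Analysis of Hi-C Chromatin Architecture with Planted-Structure Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale analysis of binned Hi-C contact matrices:
    matrix balancing, observed/expected normalization, depth downsampling and
    random-walk reproducibility scoring; global disorder metrics (contact-decay
    curves, Jensen-Shannon divergence, Von Neumann entropy, cis/trans ratio);
    A/B compartment calling with strength scores and saddle aggregation;
    insulation-score TAD and boundary detection with cross-stage sharing and
    variability ranking; simplified HiCCUPS-style loop calling with aggregate
    peak analysis and regulatory-element classification of anchors; and
    transcription-factor occupancy statistics on loop anchors. A synthetic
    contact-map generator with planted compartments, TADs, loops and paired
    gene/peak/expression annotations provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
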