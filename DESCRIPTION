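Package: bfgscreen
Title: Quantitative Readout of Barcode Fusion Genetics Yeast Two-Hybrid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational readout for pooled-matrix yeast two-hybrid
    screens that use Cre-mediated barcode fusion (BFG-Y2H). Turns fused-barcode
    amplicon reads into bait-by-prey count matrices, normalizes counts against a
    marginal non-selective model, corrects bait auto-activation background,
    combines replicate measurements into per-ORF-pair interaction scores, and
    calibrates a score cutoff by maximizing the Matthews correlation coefficient
    against a reference interaction set. Also includes a row-column-plate
    demultiplexer for barcode well decoding, an estimator of in-vivo barcode
    fusion efficiency from lox-junction reads, a forward Monte-Carlo simulator
    of the whole screen (the test oracle and an experimental-design tool), and a
    degree-preserving edge-rewiring null for network enrichment statistics.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
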