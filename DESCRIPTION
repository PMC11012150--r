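Package: bifor
Title: Quantification of Dimeric Protein Complex Enrichment at Labelled Genomic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for BiFOR-style imaging experiments, in which a
    bimolecular fluorescence complementation (BiFC) signal is quantified at a
    genomic locus labelled with the ANCHOR (ParB-INT) system in polytene
    nuclei. Provides a seeded synthetic-scene generator with ground truth,
    multi-channel TIFF and manifest input/output, DAPI-based nucleus
    segmentation, locus focus detection on the red (ParB-mCherry) channel, the
    per-nucleus enrichment ratio (maximum green intensity at the locus divided
    by the maximum over the whole nucleus), and two-condition significance
    testing with Mann-Whitney and seeded permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
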