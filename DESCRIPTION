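Package: phamflock
Title: Shared Gene Content Analysis for Bacteriophage Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clustering bacteriophage genomes by shared gene
    content rather than nucleotide identity. Groups predicted proteins
    into phams (amino-acid similarity families), computes Gene Content
    Similarity (GCS), Gene Content Dissimilarity (GCD) profiles and the
    MaxGCDGap isolation statistic, assigns clusters by connected
    components at a configurable GCS threshold, builds exact-word dot
    plots of concatenated genomes and proteomes, derives gene-content
    distance matrices with neighbor-joining trees and NEXUS export for
    split-network tools, and screens genes for horizontal gene transfer
    evidence via GC-content deviation and pham host diversity. Includes
    a synthetic phage-population generator with ground truth so every
    stage of the pipeline can be validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
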