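Package: phagesig
Title: Oligonucleotide Signature Distances for Phage Lifestyle and Host Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of phage, plasmid and bacterial host
    genomes using oligonucleotide statistics. Implements tetramer
    relative-frequency Euclidean distances (k4freq), an exact long-k-mer match
    distance (k14exact/DSW) built on a sparse k-mer counting core, hexamer
    signature clustering of host genomes (PCA + DBSCAN with noise removal),
    and ROC-based threshold selection to classify phages as lytic or
    lysogenic from their genomic distance to candidate host groups. Includes
    a synthetic genome generator for host genera, ameliorated
    (lysogenic-like) and compositionally divergent (lytic-like) phages,
    prophage insertions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
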