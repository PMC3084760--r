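Package: hcoclass
Title: Classification of Heme-Copper Oxygen Reductases and Nitric Oxide
    Reductases from Catalytic-Subunit Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate, fingerprint and classify catalytic-subunit
    (subunit I) sequences of heme-copper oxygen reductases (types A1, A2, B
    and C) and nitric oxide reductases (NOR). Implements the gold-standard
    curation filters (length, conserved histidine ligands, strain
    redundancy), residue-fingerprint typing from proton-channel residues and
    NOR sequence motifs, a best-hit annotation-transfer classifier with
    E-value acceptance and top-k agreement modes, leave-one-out benchmarking
    with per-type and global precision/recall, percent-similarity networks
    with per-cluster statistics, neighbor-joining trees from
    similarity-derived distances, and a synthetic sequence-family generator
    with planted fingerprints for offline testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
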