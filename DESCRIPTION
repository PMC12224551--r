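Package: panbgc
Title: Pan-Genome Based Detection of Conserved Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies biosynthetic gene clusters (BGCs) conserved within
    and across bacterial genera from pan-genome gene presence/absence
    matrices and annotated cluster region files. Implements per-genus
    conserved-gene detection, mapping of conserved gene families into BGC
    regions, genus-level conservation calls, phylum-level aggregation,
    presence/absence screening of additional genomes, and cluster
    comparison metrics (best-bidirectional-hit gene matching, gene-order
    synteny, fragment-based cluster nucleotide identity). Ships a
    ground-truthed synthetic data generator emitting Roary-style matrices
    and region GenBank files so the whole pipeline is testable without
    external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
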