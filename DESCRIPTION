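Package: panprobio
Title: Comparative Genomics and Gut-Microbiome Association Toolkit for
    Traditional Probiotic Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative genomic and metagenomic analysis of
    probiotic bacteria: assembly quality gates (draft-genome criteria,
    completeness/contamination, intra-species average nucleotide identity
    purity), fragment-based ANI/AAI with bidirectional averaging, greedy
    protein-family clustering with a pan-genome openness index, database
    specific annotation-hit filtering, KEGG-module integrity and pairwise
    complementarity scoring, and case/control species enrichment with
    thresholded co-abundance networks. Seeded synthetic-data generators with
    planted ground truth make every step testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
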