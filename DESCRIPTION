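Package: azaleanet
Title: Gene Duplication Modes, WGD Dating, and Time-Ordered Co-Expression
    Networks for Flower Pigmentation Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analytic chain for a chromosome-scale flowering-plant
    genome: classification of duplicated genes into whole-genome, tandem,
    proximal, transposed and dispersed duplicates from gene order and
    collinearity; Ka/Ks estimation by the Nei-Gojobori counting method with
    Jukes-Cantor correction; kernel-density detection of Ks peaks and
    rate-based dating of whole-genome duplication events; construction of
    time-ordered gene co-expression networks (TO-GCN) from a staged flower
    time course with breadth-first level assignment from a seed transcription
    factor; hierarchical regulator inference for pigment-pathway enzyme genes
    with promoter position-weight-matrix scanning; and hypergeometric
    functional enrichment with Benjamini-Hochberg correction. A synthetic-data
    module generates every input with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
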