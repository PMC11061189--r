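Package: snpool
Title: Demultiplexing and Cell-Type-Aware Analysis of Pooled Single-Nuclei RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for pooled single-nuclei RNA-seq experiments that combine
    hashtag-oligonucleotide (HTO) and genotype-based sample demultiplexing,
    with downstream cell typing, single-cell pathway enrichment scoring,
    cell-type-composition-adjusted differential expression against non-tumor
    reference tissue, and cross-group direction-concordance statistics. A
    synthetic-data generator with recorded ground truth emulates multiplexed
    pool designs (weak HTO staining, sparse per-cell SNP coverage, doublets,
    cell-type programs and composition-confounded expression) so every stage
    can be validated against known labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    cluster,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
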