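Package: crossgene
Title: Cross-Species Gene Prioritization from QTL Scans, Gene-Based GWAS and Coexpression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritizing candidate genes across species:
    positional interpolation of mouse QTL marker p-values to gene-level
    p-values, a VEGAS-style gene-based association statistic for human GWAS
    summary data with a simulated multivariate-normal null that respects
    linkage disequilibrium, cross-species concordance testing (genomic-control
    lambda with a permutation null, rank-rank hypergeometric overlap,
    Bonferroni-corrected single-gene overlap), and coexpression
    guilt-by-association machinery (probe concordance filtering, top-K
    correlate lists, multi-list intersection and two-universe overlap with
    permutation significance, and a minimal eQTL scan with cis/trans
    classification). A seeded synthetic-data generator emulates a
    recombinant-inbred cross with a planted QTL, LD-blocked GWAS summary
    statistics, an incomplete homology map, and an exon-array-like expression
    matrix, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
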