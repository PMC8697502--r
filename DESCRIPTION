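Package: pathsift
Title: Harmonize, Score, and Distill Functional Enrichment Results
Version: 0.1.0
Authors@R: person("Pathsift", "Maintainers", email = "maintainers@pathsift.dev",
    role = c("aut", "cre"))
Description: Post-processing toolkit for the interpretation step of
    transcriptomic workflows. Bundles an expression matrix, a
    differential-expression table, a functional-enrichment table and a gene
    annotation into one validated, serializable unit; converts the native
    output dialects of six popular enrichment tools into a harmonized schema;
    injects expression information into enrichment results via geneset
    Z-scores, aggregated fold changes and sample-wise geneset activity
    matrices; builds gene-geneset bipartite graphs, disparity-filter
    backbones and enrichment maps with community detection; reduces geneset
    redundancy by kappa-based fuzzy clustering and overlap filtering; and
    emits plot-data summaries plus a reproducible self-contained HTML report.
    A seeded synthetic-fixture generator with planted differential expression
    and planted enriched genesets supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    ape
Suggests:
    ggplot2,
    DESeq2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
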