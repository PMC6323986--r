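Package: netenrich
Title: Network Module Discovery and Value-Based Gene-Set Enrichment on
    Confidence-Weighted Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives data-driven "network module" gene sets from a
    confidence-weighted protein association network via diffusion state
    distance (DSD) and average-linkage hierarchical clustering, and performs
    enrichment analysis of genome-wide, value-annotated gene lists using
    hypergeometric over-representation, the Aggregate Fold Change (AFC)
    permutation test, and a rank-based Kolmogorov-Smirnov fallback for large
    sets, with Benjamini-Hochberg correction applied separately within each
    classification framework. Includes readers and writers for channel-scored
    edge lists, GMT gene-set collections, and gene-value tables, plus a
    synthetic-data generator with planted modules and planted enrichment
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
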