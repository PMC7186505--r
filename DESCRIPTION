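Package: evigene
Title: Multi-Evidence Prioritization and Network Characterization of
    Candidate Disease Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates candidate-gene lists nominated by heterogeneous
    computational prioritization methods into a cumulative evidence score,
    and characterizes the prioritized genes downstream: gene-set overlap
    enrichment with Benjamini-Hochberg and Bonferroni correction, tissue
    enrichment from a specificity-index (pSI) matrix via Fisher's exact
    test, permutation testing of interaction-network connectivity against
    random same-size gene sets, and construction of a pathway crosstalk
    network from Jaccard and overlap coefficients. Ships a synthetic-data
    generator with planted signal so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
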