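Package: CoMutNet
Title: Somatic Mutation Filtering, Recurrence and Co-Occurrence Network
    Prioritization for Small Leukemia Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to prioritize candidate driver genes in small cancer
    cohorts, developed around acute promyelocytic leukemia (APL). Provides an
    auditable somatic variant filter cascade from annotated VCF calls (matched
    remission subtraction or a germinality heuristic for unmatched samples),
    exact binomial recurrence enrichment of gene carrier frequencies against a
    reference population, chi-square mutation co-occurrence networks,
    functional-category burden and co-mutation analysis, and minimal connected
    network (MCN) analysis over a protein-protein interactome with a
    resampling null. A synthetic-data generator with planted structure makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: SomaticMutation, Network, GraphAndNetwork, VariantAnnotation,
    Software
RoxygenNote: 7.3.3
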