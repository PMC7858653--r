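Package: tknet
Title: Transkingdom Correlation Networks Linking Microbiota to Host Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs transkingdom correlation networks from 16S amplicon
    sequence variant (ASV) count tables and host immune-phenotype tables
    collected in replicated two-group experiments. Counts are singleton- and
    cumulative-abundance filtered, relativized per million, quantile
    normalized per experiment and log2 transformed; host parameters are
    normalized by birth cohort and harmonized across experiments. Per-group
    Spearman correlations are combined with a fixed-effect meta-analysis on
    Fisher's Z scale, screened by sign-consistency, fold-change-consistency
    and causality filters, and gated by class-specific false discovery rates.
    Bottleneck nodes are ranked by normalized bipartite betweenness
    centrality and calibrated against an Erdos-Renyi G(n,m) random-graph
    ensemble. A synthetic-data generator plants known microbe-host networks
    so that every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
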