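Package: metaprior
Title: Multi-Omics Meta-Analysis and Prioritization of Metabolic Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for prioritizing under-studied metabolic genes from
    multi-omics tumor data. Provides per-study two-group differential
    statistics (Mann-Whitney U, Welch t) with fold changes and prevalence
    filtering, selection of metabolic genes from enzyme commission (EC)
    annotations, a per-gene Kolmogorov-Smirnov meta-analysis of raw p-values
    across studies against a uniform null, hypergeometric pathway
    over-representation with per-omics support flags, construction of
    integrated metabolite-protein-gene biochemical networks with community
    detection and Cytoscape-compatible export, and ranking of significant
    genes by literature counts to flag under-studied candidates. Includes a
    synthetic multi-study, multi-omics data generator with known ground truth
    for calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
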