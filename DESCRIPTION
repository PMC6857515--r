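Package: coalhet
Title: Coalescent Gene-Tree Heterogeneity, Anomaly-Zone, and Retroelement
    Analytics for Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify gene-tree heterogeneity under the multispecies
    coalescent and to diagnose the anomaly zone in phylogenomic data sets.
    Provides rooted-tree cluster distances (Robinson-Foulds and matching
    cluster), gene-tree topology distributions, gene support frequencies and
    internode certainty, rooted-triplet tallies with analytic expectations,
    anomaly-zone detection from coalescent branch lengths, multispecies
    coalescent gene-tree simulation, retroelement presence/absence pattern
    classification with insertion significance tests, rooted-triplet (R*)
    species-tree estimation, phylogenomic subsampling, and synthetic data
    generators emulating a palaeognath-like radiation with two successive
    short internal branches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
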