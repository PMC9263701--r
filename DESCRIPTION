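Package: chronet
Title: Chronosequence Analysis of Soil Bacterial Communities and
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing soil bacterial communities along a
    land-use chronosequence (e.g. forest converted to long-term tea
    monoculture): rarefaction of OTU count tables, taxonomic
    aggregation, richness, Bray-Curtis dissimilarity, unconstrained
    ordination (PCoA, NMDS, PCA), PERMANOVA, distance-based redundancy
    analysis with permutation forward selection, one-way ANOVA with
    Tukey compact letter displays, and the construction and topological
    analysis of thresholded Spearman co-occurrence networks, including
    per-sample subnetworks, Erdos-Renyi null ensembles, small-world
    assessment and correlation of topology with stand age and soil
    chemistry. A Gaussian-copula synthetic community generator provides
    a ground-truth test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
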