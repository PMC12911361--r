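Package: planktonet
Title: Linking Plankton Community Structure to Ocean Biogeochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating amplicon-derived plankton community structure
    to concurrent biogeochemical measurements (net community production,
    particulate organic carbon and nitrogen) along oceanographic gradients.
    Provides ASV count-table handling (rarefaction, relative abundance,
    taxon-group assignment, persistence classification, biogeographic region
    assignment), Bray-Curtis/NMDS/ANOSIM/EnvFit community statistics,
    dissimilarity-kernel variance partitioning by multi-kernel restricted
    maximum likelihood, weighted co-abundance module detection with
    module-trait correlation, sparse compositional co-occurrence network
    inference with stability-based model selection, and integration of module
    and network views into "microbial neighborhoods". A synthetic-data
    generator with planted ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
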