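Package: covanet
Title: Protein Covariation Networks from Time-Course Immunofluorescence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific protein covariation networks from
    time-course immunofluorescence feature quantities. Provides a synthetic-data
    generator with known sparse precision-matrix ground truth, image
    segmentation and per-compartment feature quantification, sparse
    partial-correlation network estimation by the graphical lasso across a
    regularization path, node-wise correlation anomaly scores based on expected
    conditional Kullback-Leibler divergence between two Gaussian graphical
    models, overlapping link-community extraction with mean-degree selection,
    and protein-protein-interaction network expansion with Gene Ontology and
    anomaly-adjacency filters for combination-target nomination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods,
    data.table,
    igraph,
    EBImage,
    tiff,
    Rcpp,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
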