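Package: idenet
Title: Interdomain Plant-Soil Bacteria Ecological Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds and analyses bipartite interdomain ecological networks
    (IDENs) linking aboveground plant communities to soil bacterial OTUs.
    Provides SparCC compositional correlation inference with permutation
    pseudo p-values, correlation thresholding into bipartite incidence
    networks, a panel of bipartite topology metrics (connectance, web
    asymmetry, links per species, clustering, NODF nestedness, checkerboard
    C-scores, Kullback-Leibler d' specialization), fixed-fixed null-model
    significance testing, Barber bipartite modularity by simulated annealing
    with Zi-Pi node-role classification, multi-site shared-OTU comparison,
    and a seeded synthetic-data generator with planted association structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
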