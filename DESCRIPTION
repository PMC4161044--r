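Package: domClock
Title: Time-Calibrated Phylogenomic Trees of Protein Domain Abundance
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds rooted trees of protein fold superfamilies (ToD) and of
    proteomes (ToL) from genomic domain-abundance censuses by ordered-character
    (Wagner) maximum parsimony with a parsimony-ratchet search and Lundberg
    rooting against a polarization-model hypothetical ancestor. Derives
    node-distance (nd) chronologies from the rooted trees, calibrates a linear
    molecular clock against geological ages, reconstructs the urancestral
    domain repertoire at the root of the ToL, and maps superkingdom Venn
    distribution groups and whole-superkingdom domain losses. A synthetic
    census generator with recorded ground truth (domain birth times, lineage
    tree, loss events) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
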