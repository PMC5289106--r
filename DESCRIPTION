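Package: phylocatch
Title: Multilocus Phylogeography of Catchment-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus phylogeographic analysis of populations
    structured by river catchments, combined with palaeodistribution model
    post-processing. Implements intra-individual site polymorphism (2ISP)
    aware alignment encoding with IUPAC state-sets and binary indel coding,
    polymorphism p-distances, haplotype and nucleotide diversity statistics,
    permutation Mantel tests of isolation by distance, neighbour-joining
    bootstrap ensembles with the genealogical sorting index, divergence-time
    scaling under bracketing substitution rates, species distribution model
    thresholding and ensemble stacking with per-catchment area and patch
    cohesion metrics, and a seed-reproducible coalescent simulator of
    catchment-structured data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    geosphere,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
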