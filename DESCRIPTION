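Package: phylodrift
Title: Structured-Coalescent Simulation of Human-Mediated Dispersal and
    Phylogeographic Reticulation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates biallelic SNP data under a multi-deme structured
    coalescent with time-varying migration (stepping-stone natural gene flow
    plus a temporary episode of all-to-all human-mediated dispersal),
    founder events, serial sampling and RADseq-style ascertainment, and
    computes the population-genetic and phylogenetic-conflict statistics
    used to study erosion of phylogeographic structure: observed/expected
    heterozygosity, private SNPs, Reich's small-sample F_ST, hierarchical
    AMOVA, Rousset's inter-individual a-hat with isolation-by-distance
    regression, uncorrected p-distances, and quartet Delta reticulation
    scores, with NEXUS export for split-network visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
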