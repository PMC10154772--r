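Package: paleodamage
Title: Ancient-DNA Damage Simulation and Its Distortion of Population Statistics
Version: 0.1.0
Authors@R: person("Paleogenomics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates ancient-DNA sequencing libraries under different
    preparation protocols (untreated, damaged non-UDG, UDG-half) on a
    transition-rich SNP panel, calls pseudo-haploid genotypes, and quantifies
    how post-mortem cytosine deamination distorts downstream population
    statistics: ADMIXTURE-style maximum-likelihood ancestry estimation,
    F4/ABBA-BABA statistics with block-jackknife z-scores, Hudson Fst, and
    projection principal component analysis. Includes transversion-only
    masking as the mitigation strategy, EIGENSTRAT input/output, LD pruning,
    and an end-to-end protocol-comparison experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
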