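Package: demomap
Title: Spatial Maps of Dispersal and Population Density from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-trained estimation of spatially heterogeneous maps of
    per-generation dispersal rate (sigma) and population density from
    geo-referenced SNP genotypes. Provides a random generator of segmented
    demographic maps, a continuous-space individual-based forward simulator
    with ancestry recording (implemented in C++), genotype synthesis by
    coalescent completion ("recapitation") and mutation overlay to a fixed
    SNP count, three spatial sampling strategies, a two-branch pairwise
    neural network that maps genotypes and sample locations to a grid of
    demographic parameters, a training pipeline with plateau-based learning
    rate scheduling, and evaluation and uncertainty machinery (mean relative
    absolute error, ensemble prediction, parametric bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    vcfR
Config/testthat/edition: 3
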