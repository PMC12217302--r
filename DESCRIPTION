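Package: apisim
Title: Stochastic Simulation of Closed Honeybee Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of closed honeybee breeding programs with
    two-trait colony genetics. Colony phenotypes combine additive queen and
    worker-group effects under haplodiploid inheritance with polyandry.
    Provides bee-specific pedigree relationship matrices and their sparse
    inverses (queens, worker groups and open-mating pseudo-sires), a
    two-trait colony-model BLUP evaluation with average-information REML
    variance estimation, engines for a reference breeding scheme with
    two-year generation intervals and an accelerated scheme with a one-year
    dam interval and partial phenotyping, and replicate-level comparison
    statistics (relative differences, empirical superiority probabilities,
    selection intensities, inbreeding rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
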