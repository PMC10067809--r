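Package: lampetra
Title: Sperm Competition Analysis for Lamprey Ecotype Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired-male sperm-competition experiments
    between anadromous-parasitic (river lamprey, LF) and freshwater-resident
    nonparasitic (brook lamprey, LP) ecotypes. Computes computer-assisted
    sperm analysis (CASA) kinematics (curvilinear velocity VCL and
    average-path velocity VAP) from tracked sperm head coordinates,
    estimates sperm concentration from counting-chamber replicates and total
    sperm output via the gonadosomatic index, designs equal-volume and
    equal-number competitive fertilization mixes, assigns larval paternity
    from a diagnostic biallelic locus, and fits a Bayesian hierarchical
    binomial model of siring success with a built-in adaptive
    Metropolis-within-Gibbs sampler, Gelman-Rubin diagnostics, MCMC and
    posterior-predictive p-values, and per-cell departures from the fair
    raffle. A synthetic-data generator with known truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
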