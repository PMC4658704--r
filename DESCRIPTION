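Package: tideclock
Title: Expansion Dating and Coalescent Phylogeography for Mitochondrial
    Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the phylogeographic and demographic analysis of
    mitochondrial control-region alignments from recently expanded marine
    populations: diversity indices and neutrality tests (Tajima's D, Fu's Fs)
    with coalescent-simulation p-values, statistical-parsimony haplotype
    networks, genetic landscape shape interpolation over a Delaunay
    connectivity network, fixed-genealogy Bayesian inference under a two-epoch
    (constant size then exponential growth) coalescent model, marginal
    likelihoods by path sampling and stepping-stone sampling with Bayes-factor
    model comparison, and expansion dating: converting the posterior of the
    growth-onset time into a substitution-rate estimate for a geological
    calibration window. Includes a coalescent simulator (two-epoch demography,
    HKY+I sequence evolution, georeferenced sampling localities) used as the
    test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
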