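Package: mislabelGS
Title: Simulating the Impact of Genotype Mislabeling on Genomic Selection
    in Clonally Propagated Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of a recurrent genomic-selection breeding
    programme for a clonally propagated, outcrossing crop, with deliberate
    genotype-phenotype mislabeling in the training population.  Generates
    coalescent founder haplotypes with a prescribed linkage-disequilibrium
    structure, simulates meiosis and random crossing, phenotypes cohorts at
    successive trial stages with heterogeneous error variances, fits a
    weighted genomic BLUP model (heteroscedastic residuals removed by an
    R-matrix transformation, REML variance components), injects source and
    substitution labeling errors with once-only genotyping semantics, and
    provides the post-simulation statistics: genetic gain, genetic variance,
    prediction accuracy among correctly labeled clones, exact binomial tests
    of selection bias, two-way ANOVA for rate-by-scheme interaction, paired
    t tests, and the breeder's-equation response decomposition under
    mislabeling, R = (1 - e) i r sigma_A.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the msprime package, used as the
    coalescent backend for founder-haplotype simulation.
Config/testthat/edition: 3
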