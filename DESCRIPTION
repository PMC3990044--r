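Package: gxgcoev
Title: Functional and Statistical Genotype-by-Genotype Interactions in
    Host-Parasite Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and inference tools connecting mechanistic
    (functional) genotype-by-genotype infection models to the statistical
    G-by-G variance components measured in reciprocal cross-infection
    experiments. Provides matching-alleles, inverse-matching-alleles and
    gene-for-gene infection matrices with no-interaction controls; a
    Wright-Fisher coevolution simulator with selection, mutation and drift;
    simulated factorial cross-infection experiments; method-of-moments
    variance partitioning with an analytic infinite-sample oracle; and a
    latent-genotype binomial likelihood for fitting and comparing
    functional infection models directly from cross-infection tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
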