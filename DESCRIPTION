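Package: ypcgm
Title: Yield-Plasticity and Yield-Ability Coefficients from Weather-Driven
    Potential Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes multi-environment crop yield-trial data into two
    genotypic coefficients per cultivar -- yield-plasticity (alpha, the slope
    of observed yield against a theoretical potential yield) and yield-ability
    (beta, the expected yield at a standardized potential yield) -- using a
    simple weather-driven crop growth model to compute the potential yield
    from daily temperature and solar radiation. Includes the downstream
    analyses these coefficients feed: plasticity scenario simulation, genetic
    gain regression on cultivar release year, genomic and pedigree
    relationship matrices, multi-trait BLUP by Gibbs sampling with k-fold
    cross-validation and heritability estimation, mixed-linear-model GWAS
    with kinship and principal-component covariates, linkage disequilibrium,
    and haplotype group comparison. Seeded synthetic-data generators for
    weather, trial networks, genotypes, and pedigrees make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
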