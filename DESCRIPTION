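Package: meltpot
Title: Attribution of Genetic-Diversity Hotspots to Admixture and Glacial Refugia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect why hotspots of intraspecific genetic diversity
    form: prolonged bioclimatic stability within glacial refugia, or admixture
    between divergent lineages at secondary contact zones ("melting pots").
    The package computes per-population diversity statistics from aligned
    mtDNA sequences (haplotype and nucleotide diversity) and diploid
    microsatellite genotypes (observed/expected heterozygosity, rarefaction
    allelic richness), summarises externally estimated Bayesian-clustering
    output into a Simpson index of admixture, derives glacial refugia and
    stability areas from an ensemble species-distribution-modelling workflow
    (spatial thinning, VIF variable pruning, target-group background,
    AUC-weighted multi-learner ensembles, maxTSS binarisation, GCM consensus),
    and compares Gaussian GLMs of diversity on admixture and
    distance-to-refugium predictors by sequential ANOVA and AIC. A synthetic
    world generator with known drivers of diversity makes the whole pipeline
    testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
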