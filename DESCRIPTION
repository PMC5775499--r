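Package: reintropop
Title: Population Genomics of Staged Species Reintroductions
Version: 0.1.0
Authors@R:
    person("reintropop", "developers", email = "reintropop@example.org",
           role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of serial-founder species
    reintroductions with a RAD-seq-like observation model, and the population
    genomic statistics used to monitor reintroduced populations: SNP-panel
    filtering, SNP density with individual resampling, expected and observed
    heterozygosity, F_IS, Weir-Cockerham FST, genotype-covariance PCA,
    windowed runs-of-homozygosity detection with the F_ROH inbreeding
    coefficient, and effective population size estimators based on linkage
    disequilibrium, heterozygosity loss and FST accumulated by drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
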