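Package: mtgblup
Title: Single-Trait and Multi-Trait GBLUP Genomic Prediction with Forward
    Breeding Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation framework for comparing single-trait
    and bivariate (multi-trait) GBLUP genomic prediction. Generates phased
    founder genomes with tunable linkage disequilibrium, simulates F1
    offspring by meiosis under a sire-dam mating design, constructs pairs of
    genetically correlated traits through LD-matched QTL pairs carrying
    identical gamma-distributed effects, builds the VanRaden genomic
    relationship matrix, estimates variance components by average-information
    REML, and predicts breeding values for unphenotyped selection candidates.
    Includes PLINK bed/bim/fam and ped/map input/output, quality-control
    filters (call rate, minor allele frequency, exact Hardy-Weinberg test),
    and scenario drivers that quantify prediction accuracy across
    heritability, genetic-correlation and reference-size settings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
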