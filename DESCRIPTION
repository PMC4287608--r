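Package: noiseQTL
Title: Mapping Genetic Control of Stochastic Phenotypic Variation in
    Reciprocal Recombinant Inbred Line Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of stochastic (within-line)
    phenotypic variation in reciprocal recombinant inbred line (RIL)
    populations. Computes per-line, per-experiment coefficients of
    variation (CV) from replicated phenotype measurements; partitions
    phenotypic variance into nuclear, organellar (cytoplasm), experiment
    and residual components to estimate broad-sense heritabilities;
    maps mean- and variance-QTL by composite interval mapping with
    Haley-Knott regression, forward cofactor selection and permutation
    thresholds; aggregates QTL peaks into sliding-window hotspots with a
    permutation significance threshold; fits additive and pairwise
    epistasis marker ANOVA models (cytoplasm as an extra locus) with
    Type III sums of squares and FDR control, exporting epistasis
    networks; and provides a structure-preserving whole-sample
    permutation null for QTL counts. Includes a reciprocal-RIL
    simulator with separate genetic control of line means and line-level
    stochastic standard deviations so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    car,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cv.R'
    'heritability.R'
    'hotspots.R'
    'map.R'
    'markermodels.R'
    'noiseQTL-package.R'
    'permutation.R'
    'pipeline.R'
    'scan.R'
    'simulate.R'
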