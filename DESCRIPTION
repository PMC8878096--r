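Package: halott
Title: Halothermal-Time Population-Threshold Models for Seed Germination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-based threshold models for seed germination under
    combined temperature and salinity (osmotic) stress: thermal-time,
    halotime and halothermal-time models fitted by repeated probit
    regression, cardinal-temperature estimation, the supra-optimal
    threshold-shift coefficient kT, twelve classical germination indices
    (GP, MGT, GRI, GI, CVG, GE, Timson, MGR, SVI-I/II, T50, RSR),
    balanced two-way ANOVA of germination parameters, and a seed-population
    simulator for generating germination time courses with known parameters.
    Germination time courses are stored as a SummarizedExperiment-derived
    container keyed by temperature, water potential and replicate dish.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'GerminationExperiment.R'
    'curves.R'
    'indices.R'
    'threshold-models.R'
    'cardinal.R'
    'simulate.R'
    'anova.R'
    'pipeline.R'
RoxygenNote: 7.3.3
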